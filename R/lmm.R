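# Linear mixed-effects response modelling with eye-within-patient
# correlation, and backward-elimination predictor screening.

#' The default explanatory variable set for predictor screening
#'
#' Baseline demographic, systemic, ocular-history and imaging covariates,
#' including macular VD; FAZ metric columns are appended when present in the
#' eyes table so vascular shape is assessed alongside VD.
#'
#' @param eyes eyes data frame (used to keep only available columns).
#' @return character vector of column names.
#' @export
default_predictors <- function(eyes) {
  cand <- c("age", "male", "dm_type", "dm_duration", "hba1c", "insulin_use",
            "smoking", "egfr", "creatinine", "ldl_hi", "hdl_mmol_L",
            "lipid_therapy", "hypertension", "mi", "stroke", "prior_prp",
            "pseudophakic", "prior_anti_vegf", "prior_steroid",
            "prior_vitrectomy", "exudates", "microaneurysm_class",
            "leakage_pattern", "peripheral_nonperfusion", "srf", "inl_cysts",
            "onl_cysts", "dril", "intact_elm_ez", "hrf",
            "intact_terminal_ring", "perifoveal_capillary_loss", "vd",
            "faz_area_mm2", "faz_perimeter_mm", "faz_axis_ratio",
            "faz_eccentricity", "faz_acircularity")
  intersect(cand, names(eyes))
}

# Expand one predictor into model-matrix columns (treatment contrasts).
expand_predictor <- function(x, name) {
  if (is.logical(x)) {
    m <- matrix(as.numeric(x), ncol = 1)
    colnames(m) <- name
  } else if (is.numeric(x)) {
    m <- matrix(x, ncol = 1)
    colnames(m) <- name
  } else {
    f <- as.factor(x)
    if (nlevels(f) < 2L) {
      m <- matrix(numeric(length(x)), ncol = 1)
      colnames(m) <- name
    } else {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(name, ".", levels(f)[-1])
      m <- mm
    }
  }
  m
}

# Assemble the modelling frame for a response family.
build_model_frame <- function(deltas, eyes, response, visits = NULL,
                              excellent_threshold = 70,
                              final_month = NULL) {
  ekey_e <- paste(eyes$patient_id, eyes$eye)
  if (response %in% c("bcva_improvement", "crt_reduction")) {
    d <- deltas[deltas$month > 0, , drop = FALSE]
    idx <- match(paste(d$patient_id, d$eye), ekey_e)
    if (anyNA(idx)) stop("deltas contain eyes absent from the eyes table")
    df <- data.frame(
      y = if (response == "bcva_improvement") d$d_bcva_letters else d$d_crt_um,
      patient_id = d$patient_id,
      eye_uid = paste(d$patient_id, d$eye, sep = ":"),
      month = d$month,
      stringsAsFactors = FALSE
    )
    cov_rows <- eyes[idx, , drop = FALSE]
  } else if (response == "excellent_bcva") {
    if (is.null(visits)) stop("excellent_bcva requires the visits table")
    if (is.null(final_month)) final_month <- max(visits$month)
    v <- visits[visits$month == final_month, , drop = FALSE]
    idx <- match(paste(v$patient_id, v$eye), ekey_e)
    if (anyNA(idx)) stop("visits contain eyes absent from the eyes table")
    df <- data.frame(
      y = as.numeric(v$bcva_letters >= excellent_threshold),
      patient_id = v$patient_id,
      eye_uid = paste(v$patient_id, v$eye, sep = ":"),
      month = v$month,
      stringsAsFactors = FALSE
    )
    cov_rows <- eyes[idx, , drop = FALSE]
  } else stop("unknown response family: ", response)
  list(df = df, cov = cov_rows)
}

#' Fit a linear mixed-effects model for one response family
#'
#' Longitudinal responses (`bcva_improvement`, `crt_reduction`: the monthly
#' deltas from baseline) get a random intercept per patient (two eyes per
#' patient share it) and per eye (months within an eye share it), plus month
#' as a categorical fixed effect by default.  `excellent_bcva` is the
#' final-visit indicator BCVA >= 70 letters, fitted on the linear-probability
#' scale by default (so coefficients stay in letter-equivalent units) with a
#' patient random intercept; `family = "binomial"` switches to a logistic
#' GLMM.  Fixed-effect p-values are Wald normal-approximation tests;
#' multi-level categorical predictors get a joint Wald chi-square.
#'
#' With fewer than 2 two-eye patients the random effect is unidentifiable
#' and the fit degrades to fixed-effects least squares with a warning.
#'
#' @param deltas delta table from [compute_deltas()].
#' @param eyes eyes/baseline-covariate table.
#' @param response "bcva_improvement", "excellent_bcva" or "crt_reduction".
#' @param predictors character vector of eyes-table columns
#'   (default [default_predictors()]).
#' @param visits required for `excellent_bcva`.
#' @param month_as "factor" (default) or "numeric".
#' @param random "patient_eye" (default for longitudinal) or "patient".
#' @param family "gaussian" (default) or "binomial" (excellent_bcva only).
#' @param excellent_threshold letters defining an excellent outcome (70).
#' @return object of class `octa_lmm`: the fit, per-predictor p-values and
#'   leading coefficients, and bookkeeping.
#' @export
fit_lmm <- function(deltas, eyes, response, predictors = default_predictors(eyes),
                    visits = NULL, month_as = c("factor", "numeric"),
                    random = c("patient_eye", "patient"),
                    family = c("gaussian", "binomial"),
                    excellent_threshold = 70) {
  month_as <- match.arg(month_as)
  random <- match.arg(random)
  family <- match.arg(family)
  bm <- build_model_frame(deltas, eyes, response, visits, excellent_threshold)
  df <- bm$df; cov <- bm$cov

  blocks <- lapply(predictors, function(p) {
    if (!p %in% names(cov)) stop("predictor not found in eyes table: ", p)
    expand_predictor(cov[[p]], p)
  })
  names(blocks) <- predictors
  X <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow(df), 0)
  drop_na <- if (ncol(X)) !apply(X, 1, function(r) any(is.na(r))) else
    rep(TRUE, nrow(df))
  n_dropped <- sum(!drop_na)
  df <- df[drop_na, , drop = FALSE]
  X <- X[drop_na, , drop = FALSE]

  longitudinal <- response != "excellent_bcva"
  month_cols <- NULL
  if (longitudinal && length(unique(df$month)) > 1L) {
    month_cols <- if (month_as == "factor") {
      mm <- stats::model.matrix(~ factor(month), df)[, -1, drop = FALSE]
      colnames(mm) <- paste0("month.", sort(unique(df$month))[-1])
      mm
    } else {
      mm <- matrix(df$month, ncol = 1)
      colnames(mm) <- "month"
      mm
    }
  }
  Xfull <- cbind(X, month_cols)

  # rank check: report offending columns instead of silently dropping
  if (ncol(Xfull)) {
    q <- qr(cbind(1, Xfull))
    if (q$rank < ncol(Xfull) + 1L) {
      keep <- q$pivot[seq_len(q$rank)]
      bad <- setdiff(seq_len(ncol(Xfull) + 1L), keep) - 1L
      stop("rank-deficient design; offending column(s): ",
           paste(colnames(Xfull)[bad], collapse = ", "))
    }
  }

  terms <- if (is.null(Xfull) || ncol(Xfull) == 0L) character(0) else
    colnames(Xfull)
  safe <- if (length(terms)) paste0("x", seq_along(terms)) else character(0)
  if (length(terms)) colnames(Xfull) <- safe
  fit_df <- cbind(df, as.data.frame(Xfull, check.names = FALSE))
  rhs <- if (length(safe)) paste(safe, collapse = " + ") else "1"

  n_two_eye <- sum(table(unique(
    fit_df[, c("patient_id", "eye_uid")])$patient_id) >= 2L)
  degraded <- n_two_eye < 2L

  fit <- if (degraded) {
    warning("fewer than 2 two-eye patients: random intercept unidentifiable, ",
            "falling back to fixed-effects least squares")
    stats::lm(as.formula(paste("y ~", rhs)), data = fit_df)
  } else if (!longitudinal && family == "binomial") {
    lme4::glmer(as.formula(paste("y ~", rhs, "+ (1 | patient_id)")),
                data = fit_df, family = stats::binomial())
  } else {
    re <- if (longitudinal && random == "patient_eye")
      "(1 | patient_id) + (1 | eye_uid)" else "(1 | patient_id)"
    # bobyqa + no derivative check: delta responses cancel the patient
    # intercept, so its variance sits on the boundary and the default
    # optimizer's Hessian check flags spurious non-convergence
    lme4::lmer(as.formula(paste("y ~", rhs, "+", re)), data = fit_df,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  }

  est <- if (degraded) coef(fit) else lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  term_map <- lapply(blocks, function(b) match(colnames(b), terms))
  pvals <- coefs <- setNames(numeric(length(predictors)), predictors)
  for (p in predictors) {
    cols <- term_map[[p]]
    safe_cols <- safe[cols]
    b <- est[safe_cols]
    Vb <- V[safe_cols, safe_cols, drop = FALSE]
    if (length(b) == 1L) {
      z <- b / sqrt(Vb[1, 1])
      pvals[p] <- 2 * pnorm(-abs(z))
    } else {
      stat <- drop(t(b) %*% solve(Vb) %*% b)
      pvals[p] <- pchisq(stat, df = length(b), lower.tail = FALSE)
    }
    coefs[p] <- b[1L]
  }
  structure(list(
    fit = fit, response = response, predictors = predictors,
    p_values = pvals, coefficients = coefs, degraded = degraded,
    n_obs = nrow(fit_df), n_dropped_missing = n_dropped,
    family = family, month_as = month_as, random = random
  ), class = "octa_lmm")
}

#' @export
print.octa_lmm <- function(x, ...) {
  cat(sprintf("<octa_lmm> response %s, %d obs, %d predictors%s\n",
              x$response, x$n_obs, length(x$predictors),
              if (x$degraded) " (degraded to lm)" else ""))
  if (length(x$predictors)) {
    print(data.frame(coefficient = round(x$coefficients, 4),
                     p_value = signif(x$p_values, 3)))
  }
  invisible(x)
}

#' Backward-elimination predictor screening
#'
#' Iteratively refits the mixed model, at each step removing the predictor
#' with the largest p-value >= `alpha_stay`, until every remaining predictor
#' has p < `alpha_stay`.  Ties on the worst p are broken by removing the
#' predictor latest in alphabetical order (deterministic).  A refit that
#' fails keeps the would-be-removed predictor, flags it, and continues with
#' the remaining candidates.
#'
#' @inheritParams fit_lmm
#' @param alpha_stay stay threshold (default 0.05).
#' @param ... passed to [fit_lmm()].
#' @return object of class `screening_report`: per-predictor retained flag,
#'   coefficient, p-value (exit p for eliminated predictors), elimination
#'   trace, and the final fit.
#' @export
backward_eliminate <- function(deltas, eyes, response,
                               predictors = default_predictors(eyes),
                               alpha_stay = 0.05, visits = NULL, ...) {
  active <- sort(predictors)
  flagged <- character(0)
  trace <- list()
  exit_p <- exit_c <- setNames(rep(NA_real_, length(predictors)), predictors)
  step <- 0L
  removed_at <- setNames(rep(NA_integer_, length(predictors)), predictors)
  fit <- fit_lmm(deltas, eyes, response, active, visits = visits, ...)
  repeat {
    removable <- setdiff(active, flagged)
    p <- fit$p_values[removable]
    if (!length(p) || max(p) < alpha_stay) break
    worst_p <- max(p)
    cand <- names(p)[p == worst_p]
    victim <- sort(cand)[length(cand)]  # alphabetically last
    trial <- setdiff(active, victim)
    step <- step + 1L
    new_fit <- tryCatch(
      fit_lmm(deltas, eyes, response, trial, visits = visits, ...),
      error = function(e) e)
    if (inherits(new_fit, "error")) {
      flagged <- c(flagged, victim)
      trace[[step]] <- list(step = step, predictor = victim, p = worst_p,
                            action = "kept_nonconvergent",
                            message = conditionMessage(new_fit))
      next
    }
    exit_p[victim] <- worst_p
    exit_c[victim] <- fit$coefficients[victim]
    removed_at[victim] <- step
    trace[[step]] <- list(step = step, predictor = victim, p = worst_p,
                          action = "removed")
    active <- trial
    fit <- new_fit
  }
  retained <- names(exit_p) %in% active
  final_p <- exit_p
  final_c <- exit_c
  final_p[active] <- if (length(active)) fit$p_values[active] else numeric(0)
  final_c[active] <- if (length(active)) fit$coefficients[active] else numeric(0)
  structure(list(
    response = response,
    table = data.frame(
      predictor = names(exit_p),
      retained = retained,
      coefficient = unname(final_c),
      p_value = unname(final_p),
      step_removed = unname(removed_at),
      flagged_nonconvergent = names(exit_p) %in% flagged,
      stringsAsFactors = FALSE
    ),
    trace = trace,
    alpha_stay = alpha_stay,
    final_fit = fit
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %s (alpha_stay = %g)\n", x$response,
              x$alpha_stay))
  tb <- x$table
  tb$coefficient <- round(tb$coefficient, 3)
  tb$p_value <- signif(tb$p_value, 3)
  print(tb[order(-tb$retained, tb$p_value), ], row.names = FALSE)
  invisible(x)
}

#' Combine the three response families into one screening table
#'
#' One row per baseline variable with the three families' p-values,
#' significance flags at `alpha`, and coefficients for significant entries.
#' Optionally applies Benjamini-Hochberg adjustment within each family
#' (off by default, mirroring raw-p reporting).
#'
#' @param reports named list with elements `bcva_improvement`,
#'   `excellent_bcva`, `crt_reduction` ([backward_eliminate()] outputs).
#' @param alpha significance flag threshold (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return data frame (`table3`).
#' @export
build_table3 <- function(reports, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  fams <- c("bcva_improvement", "excellent_bcva", "crt_reduction")
  miss <- setdiff(fams, names(reports))
  if (length(miss)) stop("missing report(s): ", paste(miss, collapse = ", "))
  vars <- unique(unlist(lapply(fams, function(f) reports[[f]]$table$predictor)))
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (f in fams) {
    tb <- reports[[f]]$table
    idx <- match(vars, tb$predictor)
    p <- tb$p_value[idx]
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    sig <- !is.na(p) & p < alpha
    cc <- tb$coefficient[idx]
    cc[!sig] <- NA_real_
    out[[paste0("p_", f)]] <- p
    out[[paste0("sig_", f)]] <- sig
    out[[paste0("c_", f)]] <- cc
    out[[paste0("retained_", f)]] <- tb$retained[idx]
  }
  out
}
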