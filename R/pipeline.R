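# Configuration, run manifest, and the simulate | metrics | analyze | all
# command-line pipeline surface.

#' Default pipeline configuration
#'
#' Every threshold used anywhere in the pipeline, echoed into the run
#' manifest.  Unknown keys in overrides or config files are rejected.
#'
#' @param ... overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    binarize_threshold = 0.5,
    min_signal = 50,
    vd_threshold = 0.1,
    ldl_threshold = 2.6,
    excellent_threshold = 70,
    alpha_stay = 0.05,
    assumed_axial_length_mm = 23.95,
    max_bridge_px = 2L,
    n_angiograms = 8L,
    angiogram_size = 256L,
    target_density_mean = 0.098,
    target_density_sd = 0.018,
    target_density_range = c(0.05, 0.14),
    noise_sd = 0.05,
    out_dir = "octadme_out"
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a JSON pipeline configuration file (strict keys)
#' @param path JSON file.
#' @return [pipeline_config()] list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# Run manifest: config snapshot, package version, per-file hashes and the
# per-eye QC ledger, written as JSON.
write_manifest <- function(path, config, stage, files, qc = list()) {
  files <- files[file.exists(files)]
  manifest <- list(
    stage = stage,
    software = paste0("octadme ",
                      as.character(utils::packageVersion("octadme"))),
    timestamp_utc = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    file_hashes = as.list(md5sum(files)),
    qc_ledger = qc
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a full fixture directory (angiograms + cohort)
#'
#' Writes PGM angiograms with JSON sidecars (metadata + ground truth),
#' `eyes.csv`, `visits.csv`, `truth.json` and a run manifest.
#'
#' @param config [pipeline_config()].
#' @param cohort [cohort_params()] for the cohort arm.
#' @return invisibly, the output directory.
#' @export
cmd_simulate <- function(config = pipeline_config(),
                         cohort = cohort_params()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out, 2L) != 0L) stop("output directory not writable: ", out)

  set.seed(seed_substream(config$seed, "fixture-densities"))
  dens <- numeric(config$n_angiograms)
  for (i in seq_along(dens)) {
    repeat {
      d <- rnorm(1, config$target_density_mean, config$target_density_sd)
      if (d >= config$target_density_range[1] &&
          d <= config$target_density_range[2]) break
    }
    dens[i] <- d
  }
  truth_all <- list()
  img_files <- character(0)
  for (i in seq_len(config$n_angiograms)) {
    sim <- simulate_angiogram(
      size = config$angiogram_size,
      target_density = dens[i],
      noise_sd = config$noise_sd,
      # keep the FAZ a constant fraction of the field of view
      faz_semi_axes_px = round(c(28, 22) * config$angiogram_size / 256),
      seed = seed_substream(config$seed, paste0("angio-", i))
    )
    stem <- file.path(out, sprintf("angio_%03d", i))
    write_pgm(sim$angiogram$pixels, paste0(stem, ".pgm"))
    meta <- list(
      eye_id = sprintf("angio_%03d", i),
      nominal_scan_width_mm = sim$angiogram$nominal_scan_width_mm,
      signal_strength = sim$angiogram$signal_strength,
      axial_length_mm = sim$angiogram$axial_length_mm,
      truth = list(
        true_skeleton_density = sim$truth$true_skeleton_density,
        faz_ellipse = sim$truth$faz_ellipse,
        vessel_width_px = sim$truth$vessel_width_px,
        noise_sd = sim$truth$noise_sd,
        seed = sim$truth$seed
      )
    )
    jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                         digits = NA)
    truth_all[[i]] <- meta$truth
    img_files <- c(img_files, paste0(stem, ".pgm"), paste0(stem, ".json"))
  }

  sim_cohort <- simulate_cohort(cohort, seed = config$seed)
  write.csv(sim_cohort$eyes, file.path(out, "eyes.csv"), row.names = FALSE)
  write.csv(sim_cohort$visits, file.path(out, "visits.csv"),
            row.names = FALSE)
  jsonlite::write_json(truth_all, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(file.path(out, "manifest_simulate.json"), config,
                 "simulate",
                 c(img_files, file.path(out, c("eyes.csv", "visits.csv",
                                               "truth.json"))))
  invisible(out)
}

#' Measure all angiograms in a directory into a metrics CSV
#'
#' One row per eye with stable column names (vd, pd, faz_*, qc_pass).
#' Images without a sidecar, unreadable images and quality-gate failures are
#' logged in the manifest's QC ledger, never dropped silently.
#'
#' @param image_dir directory of `.pgm`/`.png` images + JSON sidecars.
#' @param config [pipeline_config()].
#' @param out_csv output CSV path (default `metrics.csv` inside `image_dir`).
#' @return invisibly, the metrics data frame.
#' @export
cmd_metrics <- function(image_dir, config = pipeline_config(),
                        out_csv = file.path(image_dir, "metrics.csv")) {
  imgs <- sort(list.files(image_dir, pattern = "\\.(pgm|png)$",
                          full.names = TRUE))
  rows <- list(); qc <- list()
  for (f in imgs) {
    sidecar <- paste0(tools::file_path_sans_ext(f), ".json")
    if (!file.exists(sidecar)) {
      qc[[length(qc) + 1L]] <- list(file = basename(f),
                                    reason = "missing sidecar; skipped")
      message("skipping ", basename(f), ": missing sidecar")
      next
    }
    a <- tryCatch(read_angiogram(f), error = function(e) e)
    if (inherits(a, "error")) {
      qc[[length(qc) + 1L]] <- list(file = basename(f),
                                    reason = paste("unreadable:",
                                                   conditionMessage(a)))
      message("skipping ", basename(f), ": unreadable image")
      next
    }
    m <- measure_eye(list(a), config = list(
      binarize_threshold = config$binarize_threshold,
      min_signal = config$min_signal,
      assumed_axial_length_mm = config$assumed_axial_length_mm,
      max_bridge_px = config$max_bridge_px
    ))
    if (!m$qc$pass) {
      qc[[length(qc) + 1L]] <- list(file = basename(f), reason = m$qc$reason)
      rows[[length(rows) + 1L]] <- data.frame(
        eye_id = a$eye_id, vd = NA_real_, pd = NA_real_,
        faz_area_mm2 = NA_real_, faz_perimeter_mm = NA_real_,
        faz_dmax_mm = NA_real_, faz_dmin_mm = NA_real_,
        faz_axis_ratio = NA_real_, faz_eccentricity = NA_real_,
        faz_acircularity = NA_real_, qc_pass = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    fz <- m$faz
    rows[[length(rows) + 1L]] <- data.frame(
      eye_id = a$eye_id,
      vd = m$density$vessel_density,
      pd = m$density$perfusion_density,
      faz_area_mm2 = if (is.null(fz)) NA_real_ else fz$area_mm2,
      faz_perimeter_mm = if (is.null(fz)) NA_real_ else fz$perimeter_mm,
      faz_dmax_mm = if (is.null(fz)) NA_real_ else fz$diameter_max_mm,
      faz_dmin_mm = if (is.null(fz)) NA_real_ else fz$diameter_min_mm,
      faz_axis_ratio = if (is.null(fz)) NA_real_ else fz$axis_ratio,
      faz_eccentricity = if (is.null(fz)) NA_real_ else fz$eccentricity,
      faz_acircularity = if (is.null(fz)) NA_real_ else fz$acircularity,
      qc_pass = TRUE,
      stringsAsFactors = FALSE)
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else data.frame(
    eye_id = character(0), vd = numeric(0), pd = numeric(0),
    faz_area_mm2 = numeric(0), faz_perimeter_mm = numeric(0),
    faz_dmax_mm = numeric(0), faz_dmin_mm = numeric(0),
    faz_axis_ratio = numeric(0), faz_eccentricity = numeric(0),
    faz_acircularity = numeric(0), qc_pass = logical(0))
  write.csv(metrics, out_csv, row.names = FALSE)
  write_manifest(file.path(dirname(out_csv), "manifest_metrics.json"),
                 config, "metrics", out_csv, qc = qc)
  if (length(qc)) message(length(qc), " image(s) logged with warnings")
  invisible(metrics)
}

#' Per-month group trajectory summary (mean change and 95% CI)
#'
#' Mean delta per month per group with mean +/- t(0.975, n-1) * SE limits,
#' the quantities plotted as trajectory error bars.
#'
#' @param deltas [compute_deltas()] output.
#' @param eyes eyes table carrying the grouping column.
#' @param group_var grouping column name in `eyes`.
#' @param outcome "d_bcva_letters" or "d_crt_um" (or another delta column).
#' @return data frame: group, month, n, mean, sd, lo, hi.
#' @export
group_trajectory_summary <- function(deltas, eyes, group_var,
                                     outcome = "d_bcva_letters") {
  idx <- match(paste(deltas$patient_id, deltas$eye),
               paste(eyes$patient_id, eyes$eye))
  g <- eyes[[group_var]][idx]
  keep <- !is.na(g)
  d <- deltas[keep, , drop = FALSE]; g <- g[keep]
  agg <- do.call(rbind, lapply(split(seq_len(nrow(d)),
                                     list(g, d$month), drop = TRUE),
    function(i) {
      v <- d[[outcome]][i]
      n <- sum(!is.na(v))
      m <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      half <- if (n > 1) qt(0.975, n - 1) * s / sqrt(n) else NA_real_
      data.frame(group = as.character(g[i[1]]), month = d$month[i[1]],
                 n = n, mean = m, sd = s, lo = m - half, hi = m + half,
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  agg[order(agg$group, agg$month), , drop = FALSE]
}

plot_trajectories <- function(summary_df, ylab, main, path) {
  pdf(path, width = 6, height = 4.5)
  on.exit(dev.off())
  groups <- unique(summary_df$group)
  cols <- c("#1b6ca8", "#c0392b", "#27ae60", "#8e44ad")[seq_along(groups)]
  rng <- range(c(summary_df$lo, summary_df$hi), na.rm = TRUE)
  plot(NA, xlim = range(summary_df$month), ylim = rng,
       xlab = "Month", ylab = ylab, main = main)
  for (k in seq_along(groups)) {
    s <- summary_df[summary_df$group == groups[k], ]
    lines(s$month, s$mean, col = cols[k], lwd = 2)
    points(s$month, s$mean, col = cols[k], pch = 16)
    ok <- !is.na(s$lo) & s$hi > s$lo
    if (any(ok))
      arrows(s$month[ok], s$lo[ok], s$month[ok], s$hi[ok], angle = 90,
             code = 3, length = 0.03, col = cols[k])
  }
  legend("topleft", legend = groups, col = cols, lwd = 2, bty = "n")
  invisible(path)
}

check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema violation in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Run the full response analysis on cohort tables
#'
#' Consumes `eyes.csv` + `visits.csv` (and optionally an OCTA metrics CSV to
#' override the eyes table's `vd`), computes deltas, runs the three
#' backward-elimination screens, and writes `table3.csv`,
#' `group_comparisons.csv`, trajectory figures and a manifest.
#'
#' @param eyes_csv,visits_csv input tables (paths or data frames).
#' @param metrics_csv optional OCTA metrics CSV with eye_id matching
#'   `patient_id:eye`.
#' @param config [pipeline_config()].
#' @param out_dir output directory (default config$out_dir).
#' @param predictors optional predictor subset for the screens.
#' @return invisibly, list with table3, reports, comparisons, summaries.
#' @export
cmd_analyze <- function(eyes_csv, visits_csv, metrics_csv = NULL,
                        config = pipeline_config(),
                        out_dir = config$out_dir,
                        predictors = NULL) {
  eyes <- if (is.data.frame(eyes_csv)) eyes_csv else
    read.csv(eyes_csv, stringsAsFactors = FALSE)
  visits <- if (is.data.frame(visits_csv)) visits_csv else
    read.csv(visits_csv, stringsAsFactors = FALSE)
  check_schema(eyes, c("patient_id", "eye", "vd", "ldl_mmol_L"), "eyes")
  check_schema(visits, c("patient_id", "eye", "month", "bcva_letters",
                         "crt1_um"), "visits")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(metrics_csv)) {
    metrics <- if (is.data.frame(metrics_csv)) metrics_csv else
      read.csv(metrics_csv, stringsAsFactors = FALSE)
    check_schema(metrics, c("eye_id", "vd"), "metrics")
    idx <- match(paste(eyes$patient_id, eyes$eye, sep = ":"),
                 metrics$eye_id)
    hit <- !is.na(idx)
    eyes$vd[hit] <- metrics$vd[idx[hit]]
  }

  n_in <- nrow(eyes)
  excluded <- list()
  vd_missing <- is.na(eyes$vd)
  if (any(vd_missing)) {
    excluded <- c(excluded, lapply(which(vd_missing), function(i) {
      list(eye = paste(eyes$patient_id[i], eyes$eye[i]),
           reason = "VD ungradable: excluded from VD-stratified analyses")
    }))
  }

  eyes <- dichotomize(eyes, "vd", config$vd_threshold, "vd_hi")
  eyes <- dichotomize(eyes, "ldl_mmol_L", config$ldl_threshold, "ldl_hi")
  deltas <- compute_deltas(visits)

  preds <- predictors %||% default_predictors(eyes)
  eyes_ok <- eyes[!vd_missing, , drop = FALSE]
  keep_key <- paste(eyes_ok$patient_id, eyes_ok$eye)
  deltas_ok <- deltas[paste(deltas$patient_id, deltas$eye) %in% keep_key, ,
                      drop = FALSE]
  visits_ok <- visits[paste(visits$patient_id, visits$eye) %in% keep_key, ,
                      drop = FALSE]
  reports <- list(
    bcva_improvement = backward_eliminate(
      deltas_ok, eyes_ok, "bcva_improvement", preds,
      alpha_stay = config$alpha_stay),
    excellent_bcva = backward_eliminate(
      deltas_ok, eyes_ok, "excellent_bcva", preds,
      alpha_stay = config$alpha_stay, visits = visits_ok,
      excellent_threshold = config$excellent_threshold),
    crt_reduction = backward_eliminate(
      deltas_ok, eyes_ok, "crt_reduction", preds,
      alpha_stay = config$alpha_stay)
  )
  t3 <- build_table3(reports)
  write.csv(t3, file.path(out_dir, "table3.csv"), row.names = FALSE)

  # univariate group comparisons at the published thresholds
  final_m <- max(deltas$month)
  d6 <- deltas[deltas$month == final_m, , drop = FALSE]
  ekey <- paste(eyes$patient_id, eyes$eye)
  comp_one <- function(group_var, outcome, label) {
    g <- eyes[[group_var]][match(paste(d6$patient_id, d6$eye), ekey)]
    v <- d6[[outcome]]
    ok <- !is.na(g) & !is.na(v)
    if (length(unique(g[ok])) != 2L) return(NULL)
    lv <- sort(unique(as.character(g[ok])))
    cmp <- compare_groups(v[ok & as.character(g) == lv[2]],
                          v[ok & as.character(g) == lv[1]],
                          method = "t", group_names = rev(lv))
    data.frame(comparison = label, group_var = group_var, outcome = outcome,
               n1 = cmp$groups$n[1], mean1 = cmp$groups$mean[1],
               sd1 = cmp$groups$sd[1], n2 = cmp$groups$n[2],
               mean2 = cmp$groups$mean[2], sd2 = cmp$groups$sd[2],
               statistic = cmp$statistic, p_value = cmp$p_value,
               test = cmp$test, stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, Filter(Negate(is.null), list(
    comp_one("vd_hi", "d_bcva_letters", "BCVA change by VD group"),
    comp_one("vd_hi", "d_crt_um", "CRT change by VD group"),
    comp_one("ldl_hi", "d_bcva_letters", "BCVA change by LDL group"),
    comp_one("ldl_hi", "d_crt_um", "CRT change by LDL group"),
    comp_one("peripheral_nonperfusion", "d_crt_um",
             "CRT change by peripheral non-perfusion"),
    comp_one("peripheral_nonperfusion", "d_bcva_letters",
             "BCVA change by peripheral non-perfusion")
  )))
  write.csv(comparisons, file.path(out_dir, "group_comparisons.csv"),
            row.names = FALSE)

  summaries <- list()
  figs <- character(0)
  specs <- list(
    list(gv = "vd_hi", oc = "d_bcva_letters",
         ylab = "BCVA change (letters)", file = "fig_bcva_by_vd.pdf"),
    list(gv = "vd_hi", oc = "d_crt_um",
         ylab = "CRT change (um)", file = "fig_crt_by_vd.pdf"),
    list(gv = "ldl_hi", oc = "d_bcva_letters",
         ylab = "BCVA change (letters)", file = "fig_bcva_by_ldl.pdf"),
    list(gv = "peripheral_nonperfusion", oc = "d_crt_um",
         ylab = "CRT change (um)", file = "fig_crt_by_np.pdf")
  )
  for (sp in specs) {
    if (!sp$gv %in% names(eyes)) next
    sm <- group_trajectory_summary(deltas, eyes, sp$gv, sp$oc)
    summaries[[paste(sp$gv, sp$oc, sep = ".")]] <- sm
    fp <- file.path(out_dir, sp$file)
    plot_trajectories(sm, sp$ylab, paste(sp$oc, "by", sp$gv), fp)
    figs <- c(figs, fp)
  }
  qc <- c(excluded,
          list(list(rows_in = n_in,
                    rows_analyzed = n_in - sum(vd_missing),
                    rows_excluded = sum(vd_missing))))
  write_manifest(file.path(out_dir, "manifest_analyze.json"), config,
                 "analyze",
                 c(file.path(out_dir, c("table3.csv",
                                        "group_comparisons.csv")), figs),
                 qc = qc)
  invisible(list(table3 = t3, reports = reports, comparisons = comparisons,
                 summaries = summaries))
}

#' Command-line entry point
#'
#' Subcommands: `simulate | metrics | analyze | all`, with flags `--config
#' <json>`, `--seed <int>`, `--out <dir>`.  Exit status (returned invisibly):
#' 0 ok, 1 usage error, 2 data error.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the exit status.
#' @export
octadme_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: octadme <simulate|metrics|analyze|all> [--config cfg.json]",
        "[--seed N] [--out DIR]\n")
  }
  if (!length(args)) { usage(); return(invisible(1L)) }
  cmd <- args[[1L]]
  rest <- args[-1L]
  opt <- list(config = NULL, seed = NULL, out = NULL)
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    if (!key %in% names(opt) || i == length(rest)) { usage(); return(invisible(1L)) }
    opt[[key]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  cfg <- tryCatch({
    base <- if (is.null(opt$config)) pipeline_config() else
      read_config(opt$config)
    if (!is.null(opt$seed)) base$seed <- as.integer(opt$seed)
    if (!is.null(opt$out)) base$out_dir <- opt$out
    base
  }, error = function(e) e)
  if (inherits(cfg, "error")) {
    message("config error: ", conditionMessage(cfg))
    return(invisible(1L))
  }
  run <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message("error: ", conditionMessage(e)); 2L
    })
  }
  status <- switch(cmd,
    simulate = run(cmd_simulate(cfg)),
    metrics = run(cmd_metrics(cfg$out_dir, cfg)),
    analyze = run(cmd_analyze(file.path(cfg$out_dir, "eyes.csv"),
                              file.path(cfg$out_dir, "visits.csv"),
                              config = cfg)),
    all = run({
      cmd_simulate(cfg)
      cmd_metrics(cfg$out_dir, cfg)
      cmd_analyze(file.path(cfg$out_dir, "eyes.csv"),
                  file.path(cfg$out_dir, "visits.csv"),
                  config = cfg)
    }),
    { usage(); 1L }
  )
  invisible(status)
}
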