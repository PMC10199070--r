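quiet_cohort <- function(seed, effects = NULL) {
  p <- cohort_params(
    extra_effects = list(bcva = effects, crt = NULL),
    trajectories = list(
      bcva = list(group = "vd_hi",
                  change = list("TRUE" = rep(0, 7), "FALSE" = rep(0, 7)),
                  baseline = c("TRUE" = 71, "FALSE" = 71)),
      crt = cohort_params()$trajectories$crt
    ))
  simulate_cohort(p, seed = seed)
}

test_that("zero patient-intercept generator yields near-zero fitted RE variance", {
  p <- cohort_params(sd_patient_intercept_bcva = 0, sd_residual_bcva = 3)
  ch <- simulate_cohort(p, seed = 2)
  d <- compute_deltas(ch$visits)
  f <- fit_lmm(d, ch$eyes, "bcva_improvement", predictors = "vd")
  vc <- as.data.frame(lme4::VarCorr(f$fit))
  v_pat <- vc$vcov[vc$grp == "patient_id"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  expect_lt(v_pat / v_res, 0.15)
})

test_that("fixed effects are invariant under eye relabeling", {
  ch <- quiet_cohort(5, effects = c(vd = 120))
  d <- compute_deltas(ch$visits)
  f1 <- fit_lmm(d, ch$eyes, "bcva_improvement", predictors = c("vd", "age"))
  # swap OD/OS labels everywhere
  swap <- function(e) ifelse(e == "OD", "OS", "OD")
  ch$eyes$eye <- swap(ch$eyes$eye)
  d$eye <- swap(d$eye)
  f2 <- fit_lmm(d, ch$eyes, "bcva_improvement", predictors = c("vd", "age"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$p_values, f2$p_values, tolerance = 1e-5)
})

test_that("an injected 120 letters-per-unit-VD effect is recovered", {
  ch <- quiet_cohort(7, effects = c(vd = 120))
  d <- compute_deltas(ch$visits)
  f <- fit_lmm(d, ch$eyes, "bcva_improvement",
               predictors = c("vd", "age", "male"))
  se <- abs(f$coefficients["vd"] /
              qnorm(f$p_values["vd"] / 2, lower.tail = FALSE))
  expect_lt(abs(f$coefficients["vd"] - 120), 2.5 * se)
})

test_that("rank-deficient designs report the offending column", {
  ch <- quiet_cohort(3)
  ch$eyes$vd_copy <- ch$eyes$vd
  d <- compute_deltas(ch$visits)
  expect_error(fit_lmm(d, ch$eyes, "bcva_improvement",
                       predictors = c("vd", "vd_copy")),
               "rank-deficient.*vd_copy")
})

test_that("single-eye cohorts degrade to fixed-effects with a warning", {
  p <- cohort_params(n_patients = 30L, p_second_eye = 0)
  ch <- simulate_cohort(p, seed = 8)
  d <- compute_deltas(ch$visits)
  expect_warning(f <- fit_lmm(d, ch$eyes, "excellent_bcva",
                              predictors = "vd", visits = ch$visits),
                 "fewer than 2 two-eye")
  expect_true(f$degraded)
  expect_s3_class(f$fit, "lm")
})

test_that("backward elimination: empty set gives an intercept-only report", {
  ch <- quiet_cohort(4)
  d <- compute_deltas(ch$visits)
  rep0 <- backward_eliminate(d, ch$eyes, "bcva_improvement",
                             predictors = character(0))
  expect_equal(nrow(rep0$table), 0L)
  expect_length(rep0$trace, 0L)
})

test_that("backward elimination is invariant to predictor input order", {
  ch <- quiet_cohort(9, effects = c(vd = 120))
  d <- compute_deltas(ch$visits)
  preds <- c("vd", "age", "male", "smoking", "hba1c")
  r1 <- backward_eliminate(d, ch$eyes, "bcva_improvement", preds)
  r2 <- backward_eliminate(d, ch$eyes, "bcva_improvement", rev(preds))
  t1 <- r1$table[order(r1$table$predictor), ]
  t2 <- r2$table[order(r2$table$predictor), ]
  expect_equal(t1$retained, t2$retained)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-8)
})

test_that("retained predictors all beat the stay threshold", {
  ch <- quiet_cohort(10, effects = c(vd = 150))
  d <- compute_deltas(ch$visits)
  rp <- backward_eliminate(d, ch$eyes, "bcva_improvement",
                           c("vd", "age", "male", "smoking"))
  kept <- rp$table[rp$table$retained & !rp$table$flagged_nonconvergent, ]
  expect_true(all(kept$p_value < rp$alpha_stay))
  gone <- rp$table[!rp$table$retained, ]
  expect_true(all(!is.na(gone$p_value)))   # eliminated carry their exit p
  expect_true(all(!is.na(gone$step_removed)))
})

test_that("a strong predictor survives among nulls in a single cohort", {
  ch <- quiet_cohort(11, effects = c(vd = 250))
  d <- compute_deltas(ch$visits)
  rp <- backward_eliminate(d, ch$eyes, "bcva_improvement",
                           c("vd", "age", "male", "smoking", "hba1c",
                             "insulin_use"))
  expect_true(rp$table$retained[rp$table$predictor == "vd"])
})

test_that("the three response families assemble into one table", {
  ch <- quiet_cohort(12, effects = c(vd = 150))
  d <- compute_deltas(ch$visits)
  preds <- c("vd", "age", "male")
  reports <- list(
    bcva_improvement = backward_eliminate(d, ch$eyes, "bcva_improvement",
                                          preds),
    excellent_bcva = backward_eliminate(d, ch$eyes, "excellent_bcva", preds,
                                        visits = ch$visits),
    crt_reduction = backward_eliminate(d, ch$eyes, "crt_reduction", preds)
  )
  t3 <- build_table3(reports)
  expect_setequal(t3$variable, preds)
  expect_true(all(c("p_bcva_improvement", "p_excellent_bcva",
                    "p_crt_reduction") %in% names(t3)))
  expect_true(all(t3$p_bcva_improvement >= 0 & t3$p_bcva_improvement <= 1,
                  na.rm = TRUE))
  # coefficients attached only for significant entries
  expect_true(all(is.na(t3$c_bcva_improvement[!t3$sig_bcva_improvement])))
  # deterministic given the fitted bundle
  expect_identical(t3, build_table3(reports))
  expect_error(build_table3(reports[1:2]), "missing report")
  # no-significance family flags nothing
  null_rep <- backward_eliminate(d, ch$eyes, "crt_reduction",
                                 c("age", "male"))
  reports$crt_reduction <- null_rep
  t3b <- build_table3(reports)
  if (all(!t3b$sig_crt_reduction, na.rm = TRUE))
    expect_true(all(is.na(t3b$c_crt_reduction)))
})

test_that("logistic arm runs for the excellent-outcome family", {
  ch <- quiet_cohort(13)
  d <- compute_deltas(ch$visits)
  f <- fit_lmm(d, ch$eyes, "excellent_bcva", predictors = "vd",
               visits = ch$visits, family = "binomial")
  expect_true(is.finite(f$p_values["vd"]))
})
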