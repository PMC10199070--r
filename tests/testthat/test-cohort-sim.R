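test_that("cohort size matches the 76-eye / 48-patient design", {
  n_eyes <- vapply(1:20, function(s)
    nrow(simulate_cohort(seed = s)$eyes), numeric(1))
  # E[eyes] = 48 * (1 + 28/48) = 76; binomial sd ~ 2.4
  expect_gt(mean(n_eyes), 76 - 2 * 2.4 / sqrt(20))
  expect_lt(mean(n_eyes), 76 + 2 * 2.4 / sqrt(20))
  ch <- simulate_cohort(seed = 3)
  per_pat <- table(ch$eyes$patient_id)
  expect_true(all(per_pat %in% 1:2))
  expect_equal(length(unique(ch$eyes$patient_id)), 48L)
})

test_that("noise-free limit reproduces the subgroup trajectories exactly", {
  p <- cohort_params(sd_patient_intercept_bcva = 0, sd_residual_bcva = 0,
                     sd_patient_intercept_crt = 0, sd_residual_crt = 0)
  ch <- simulate_cohort(p, seed = 4)
  d <- compute_deltas(ch$visits)
  for (lev in c(TRUE, FALSE)) {
    eyeset <- paste(ch$eyes$patient_id, ch$eyes$eye)[ch$eyes$vd_hi == lev]
    rows <- paste(d$patient_id, d$eye) %in% eyeset
    tr <- p$trajectories$bcva$change[[as.character(lev)]]
    for (m in 0:6) {
      vals <- d$d_bcva_letters[rows & d$month == m]
      expect_equal(unname(vals), rep(tr[m + 1], length(vals)))
    }
  }
  for (lev in c(TRUE, FALSE)) {
    eyeset <- paste(ch$eyes$patient_id, ch$eyes$eye)[
      ch$eyes$peripheral_nonperfusion == lev]
    rows <- paste(d$patient_id, d$eye) %in% eyeset
    tr <- p$trajectories$crt$change[[as.character(lev)]]
    vals6 <- d$d_crt_um[rows & d$month == 6]
    expect_equal(unname(vals6), rep(tr[7], length(vals6)))
  }
})

test_that("both eyes of a patient share patient-level fields and intercept", {
  ch <- simulate_cohort(seed = 9)
  two <- names(which(table(ch$eyes$patient_id) == 2L))
  expect_gt(length(two), 5)
  pat_cols <- c("age", "male", "dm_type", "hba1c", "ldl_mmol_L", "egfr",
                "smoking", "hypertension")
  for (pid in two) {
    rows <- ch$eyes[ch$eyes$patient_id == pid, pat_cols]
    for (cl in pat_cols)
      expect_identical(rows[[cl]][1], rows[[cl]][2], info = paste(pid, cl))
  }
  # exchangeability: shuffling eye order leaves patient-level fields intact
  shuffled <- ch$eyes[sample(nrow(ch$eyes)), ]
  merged <- merge(unique(ch$eyes[, c("patient_id", pat_cols)]),
                  unique(shuffled[, c("patient_id", pat_cols)]),
                  by = "patient_id")
  expect_equal(nrow(merged), 48L)
})

test_that("patient-intercept variance converges at n = 2000 (within 10%)", {
  p <- cohort_params(
    n_patients = 2000L, p_second_eye = 0,
    sd_patient_intercept_bcva = 12, sd_residual_bcva = 0,
    months = c(0L, 1L),
    trajectories = list(
      bcva = list(group = "vd_hi",
                  change = list("TRUE" = c(0, 0), "FALSE" = c(0, 0)),
                  baseline = c("TRUE" = 70, "FALSE" = 70)),
      crt = list(group = "peripheral_nonperfusion",
                 change = list("TRUE" = c(0, 0), "FALSE" = c(0, 0)),
                 baseline = c("TRUE" = 400, "FALSE" = 400))
    ))
  ch <- simulate_cohort(p, seed = 21)
  base <- ch$visits$bcva_letters[ch$visits$month == 0]
  expect_lt(abs(var(base) - 144) / 144, 0.10)
})

test_that("undefined subgroup level in the trajectory table errors", {
  p <- cohort_params()
  p$trajectories$bcva$change[["FALSE"]] <- NULL
  p$trajectories$bcva$baseline <- p$trajectories$bcva$baseline["TRUE"]
  expect_error(simulate_cohort(p, seed = 1), "undefined subgroup")
})

test_that("parameter validation rejects malformed trajectories", {
  expect_error(cohort_params(months = c(0, 2, 1)), "increasing|length")
  bad <- cohort_params()
  bad$trajectories$bcva$change[["TRUE"]][1] <- 5
  expect_error(octadme:::validate_cohort_params(bad), "month-0")
  expect_error(cohort_params(nonsense = 1), "unknown")
})

test_that("clamps hold: BCVA in [0, 100], CRT floored", {
  p <- cohort_params(sd_residual_bcva = 40, sd_residual_crt = 300)
  ch <- simulate_cohort(p, seed = 6)
  expect_true(all(ch$visits$bcva_letters >= 0 & ch$visits$bcva_letters <= 100))
  expect_true(all(ch$visits$crt1_um >= 150))
})

test_that("dropout and VD-missing knobs work and default off", {
  ch0 <- simulate_cohort(seed = 12)
  expect_false(any(ch0$eyes$vd_missing))
  expect_equal(nrow(ch0$visits), nrow(ch0$eyes) * 7L)
  p <- cohort_params(dropout_prob = 0.15, p_vd_missing = 0.2)
  ch <- simulate_cohort(p, seed = 12)
  expect_lt(nrow(ch$visits), nrow(ch$eyes) * 7L)
  # every eye keeps its baseline row
  expect_true(all(paste(ch$eyes$patient_id, ch$eyes$eye) %in%
    paste(ch$visits$patient_id, ch$visits$eye)[ch$visits$month == 0]))
  expect_gt(sum(ch$eyes$vd_missing), 0)
  expect_true(all(is.na(ch$eyes$vd[ch$eyes$vd_missing])))
})

test_that("subgroup mean recovery: VD-high month-6 BCVA gain over cohorts", {
  means <- vapply(1:30, function(s) {
    ch <- simulate_cohort(seed = 300 + s)
    d <- compute_deltas(ch$visits)
    hi <- paste(ch$eyes$patient_id, ch$eyes$eye)[ch$eyes$vd_hi]
    mean(d$d_bcva_letters[d$month == 6 & paste(d$patient_id, d$eye) %in% hi])
  }, numeric(1))
  # generator target 6.7; MC standard error of the grand mean ~ 0.23
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 6.7), 3 * se + 0.05)
})
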