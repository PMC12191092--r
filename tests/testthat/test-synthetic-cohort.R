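test_that("config validation rejects malformed fields by name", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(n_years = 1), "n_years")
  expect_error(cohort_config(arm_probabilities = c(0.5, 0.5, 0.5)),
               "arm_probabilities")
  expect_error(cohort_config(missingness_params = list(
    pattern_weights = c(0.5, 0.5, 0.5, 0.5), p_missing_drive = 0.6,
    p_missing_transit = 0.8, p_has_wheelchair = 0.03)), "pattern_weights")
  expect_error(cohort_config(missingness_params = list(
    pattern_weights = c(1, 0, 0, 0), p_missing_drive = 1.6,
    p_missing_transit = 0.8, p_has_wheelchair = 0.03)), "p_missing_drive")
  bad_scales <- fabwork:::fab_scale_defaults()
  bad_scales$base_sd[1] <- 0
  expect_error(cohort_config(scale_params = bad_scales), "strictly positive")
})

test_that("generation is deterministic given config and seed", {
  cfg <- test_cohort_config(n = 80, seed = 11,
                            missing_patterns = c(0.4, 0.3, 0.2, 0.1))
  p1 <- suppressWarnings(generate_cohort(cfg))
  p2 <- suppressWarnings(generate_cohort(cfg))
  expect_identical(p1$data, p2$data)
  expect_identical(p1$mask, p2$mask)
  expect_identical(p1$truth, p2$truth)
})

test_that("cohort has the configured participant count and panel shape", {
  cfg <- test_cohort_config(n = 120, seed = 3)
  p <- suppressWarnings(generate_cohort(cfg))
  expect_equal(length(unique(p$data$participant)), 120)
  expect_equal(nrow(p$data), 120 * 4)
  ## exactly one row per participant-year
  expect_true(all(table(p$data$participant, p$data$year) == 1))
  ## demographics constant within participant
  split_edu <- tapply(p$data$education, p$data$participant,
                      function(x) length(unique(x)))
  expect_true(all(split_edu == 1))
  ## counts non-negative
  expect_true(all(p$data$total_er_visits >= 0))
})

test_that("functional trajectories reproduce configured moments", {
  cfg <- cohort_config(n_participants = 10000, seed = 5)
  set.seed(5)
  arr <- sample_fab_trajectory(cfg, n = 10000)
  sp <- cfg$scale_params
  ## baseline mean within 3 standard errors per scale
  for (k in seq_len(nrow(sp))) {
    se <- sp$base_sd[k] / sqrt(10000)
    expect_lt(abs(mean(arr[, 1, k]) - sp$base_mean[k]), 3 * se)
  }
  ## year-2 change of Communication & Cognition near 0.7
  ch2 <- arr[, 3, "comm_cognition"] - arr[, 1, "comm_cognition"]
  expect_lt(abs(mean(ch2) - 0.7), 3 * 7.0 / sqrt(10000))
  ## baseline Resilience SD within 5% of 9.6
  expect_lt(abs(sd(arr[, 1, "resilience"]) - 9.6), 0.05 * 9.6)
  ## degenerate change SD: year value = baseline + change mean exactly
  cfg0 <- cfg
  for (t in 1:3) cfg0$scale_params[[paste0("d", t, "_sd")]][] <- 0
  set.seed(1)
  a0 <- sample_fab_trajectory(cfg0, n = 50)
  expect_equal(a0[, 2, 1], a0[, 1, 1] + cfg0$scale_params$d1_mean[1])
})

test_that("medical trajectories match configured moments and edge cases", {
  cfg <- cohort_config(n_participants = 10000, seed = 6)
  set.seed(6)
  arr <- suppressWarnings(sample_medical_counts(cfg, n = 10000))
  ## baseline CSI near 25.2, baseline total ER visits near 1.2
  expect_lt(abs(mean(arr[, 1, "csi"]) - 25.2), 3 * 11.2 / sqrt(10000))
  expect_lt(abs(mean(arr[, 1, "total_er_visits"]) - 1.2), 3 * 1.9 / sqrt(10000))
  expect_lt(abs(sd(arr[, 1, "bmi"]) - 8.9), 0.05 * 8.9)
  expect_true(all(arr >= 0))
  ## zero-mean count variable draws all zeros
  cfg0 <- cfg
  cfg0$medical_params$base_mean[cfg0$medical_params$variable == "total_er_visits"] <- 0
  set.seed(1)
  a0 <- suppressWarnings(sample_medical_counts(cfg0, n = 30))
  expect_true(all(a0[, 1, "total_er_visits"] == 0))
  ## SD^2 <= mean falls back to Poisson with a warning
  cfgp <- cohort_config(n_participants = 10, seed = 1)
  cfgp$medical_params <- cfgp$medical_params[
    cfgp$medical_params$variable == "total_er_visits", ]
  cfgp$medical_params$base_sd <- 0.5   # var 0.25 < mean 1.2
  set.seed(2)
  expect_warning(sample_medical_counts(cfgp, n = 100), "Poisson")
})

test_that("missingness patterns blank whole waves in units of 7", {
  cfg <- test_cohort_config(n = 600, seed = 9,
                            missing_patterns = c(0.4, 0.3, 0.2, 0.1))
  p <- suppressWarnings(generate_cohort(cfg))
  counts <- missing_measurements(p)
  expect_true(all(counts %in% c(0, 7, 14, 21)))
  ## fraction with pattern 21 near its weight
  f21 <- mean(counts == 21)
  expect_lt(abs(f21 - 0.1), 3 * sqrt(0.1 * 0.9 / 600))
  ## no baseline scores are ever blanked
  expect_true(all(!p$mask[p$data$year == 0, ]))
  ## all-observed pattern: nothing missing anywhere
  p0 <- suppressWarnings(generate_cohort(test_cohort_config(n = 60, seed = 2)))
  expect_equal(sum(p0$mask), 0)
})

test_that("Community Mobility presence rates match configuration", {
  cfg <- test_cohort_config(n = 2500, seed = 13)
  p <- suppressWarnings(generate_cohort(cfg))
  n_rows <- nrow(p$data)
  expect_lt(abs(mean(p$data$has_drive) - 0.40), 3 * sqrt(0.4 * 0.6 / n_rows))
  expect_lt(abs(mean(p$data$has_ride) - 0.20), 3 * sqrt(0.2 * 0.8 / n_rows))
})

test_that("truth channel round-trips: unmasking restores the panel", {
  cfg <- test_cohort_config(n = 150, seed = 21,
                            missing_patterns = c(0.25, 0.25, 0.25, 0.25))
  p <- suppressWarnings(generate_cohort(cfg))
  expect_gt(sum(p$mask), 0)
  restored <- unmask_panel(p)
  expect_false(anyNA(restored$data[, colnames(p$mask)]))
  expect_equal(as.matrix(restored$data[, colnames(p$mask)]), p$truth,
               ignore_attr = TRUE)
})

test_that("outcome mechanism matches its logistic closed form", {
  ## zero coefficients, intercept 0: prevalence near 1/2
  cfg <- test_cohort_config(n = 1500, seed = 31, beta = c(baseline_working = 0))
  cfg$outcome_params <- list(alpha = 0, beta = c(baseline_working = 0))
  p <- suppressWarnings(generate_cohort(cfg))
  y <- p$data$steady_work[p$data$year > 0]
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / length(y)))
  ## named coefficient absent from the design errors
  expect_error(
    sample_outcome(matrix(0, 5, 1, dimnames = list(NULL, "x")),
                   rep(1L, 5), list(alpha = 0, beta = c(nope = 1))),
    "absent")
})

test_that("panel CSV round-trip preserves data, mask and truth", {
  cfg <- test_cohort_config(n = 40, seed = 41,
                            missing_patterns = c(0.5, 0.5, 0, 0))
  p <- suppressWarnings(generate_cohort(cfg))
  stem <- file.path(tempdir(), "panel_rt")
  write_panel(p, stem)
  p2 <- read_panel(stem)
  expect_equal(p2$data$steady_work, p$data$steady_work)
  expect_equal(unname(p2$mask), unname(p$mask))
  expect_equal(unname(as.matrix(p2$truth)), unname(p$truth), tolerance = 1e-12)
  unlink(paste0(stem, c(".csv", "_mask.csv", "_truth.csv", "_config.json")))
})
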