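## Default calibration tables for the synthetic cohort.
##
## Scale scores sit on the WD-FAB T-score-like metric (population mean 50,
## SD 10 in the instrument's norming sample; this cohort scores well below
## that). Moments are per study year: a baseline mean/SD plus, for each
## post-baseline year, the mean/SD of the change from baseline.

fab_scale_defaults <- function() {
  data.frame(
    scale = c("fine_motor", "upper_body", "comm_cognition", "basic_mobility",
              "resilience", "interpersonal", "mood_emotions"),
    base_mean = c(43.0, 39.4, 41.8, 40.2, 47.6, 44.4, 38.6),
    base_sd   = c(5.6, 5.8, 6.6, 6.0, 9.6, 8.8, 12.0),
    d1_mean   = c(-0.5, -0.2, 0.7, 0.3, 0.2, 2.1, 4.0),
    d1_sd     = c(5.6, 4.8, 6.7, 4.8, 10.1, 10.6, 12.9),
    d2_mean   = c(0.4, 0.3, 0.7, 0.1, 1.2, 1.3, 1.3),
    d2_sd     = c(5.5, 5.0, 7.0, 4.9, 10.1, 12.2, 13.5),
    d3_mean   = c(0.0, 0.2, 0.5, 0.1, 0.5, 1.0, 1.0),
    d3_sd     = c(5.2, 4.7, 7.1, 4.5, 10.3, 12.1, 12.7),
    stringsAsFactors = FALSE
  )
}

## Medical variables: four screening/assessment scores handled as
## zero-truncated continuous measures with a baseline + change trajectory,
## and 25 utilization counts drawn per-year from over-dispersed count
## distributions matched to the year-specific mean/SD.
## `subset = "core"` keeps the 8 highest-signal variables, useful for
## reduced-scale simulation studies where the ultra-rare utilization
## counts would be degenerate (all-zero) at small n.
medical_defaults <- function(subset = c("all", "core")) {
  subset <- match.arg(subset)
  score <- data.frame(
    variable = c("csi", "bmi", "dast", "audit"),
    type = "score",
    base_mean = c(25.2, 31.1, 1.1, 3.5),
    base_sd   = c(11.2, 8.9, 2.0, 5.7),
    d1_mean = c(-3.0, -0.2, -0.5, -0.7),
    d1_sd   = c(10.7, 3.7, 1.9, 4.9),
    d2_mean = c(-2.0, 0.1, 0.0, -0.1),
    d2_sd   = c(10.2, 3.2, 1.6, 4.5),
    d3_mean = c(-1.0, 0.3, 0.0, -0.1),
    d3_sd   = c(9.7, 3.3, 1.5, 4.1),
    stringsAsFactors = FALSE
  )
  cnt <- function(variable, y0, y1, y2, y3) {
    data.frame(variable = variable, type = "count",
               base_mean = y0[1], base_sd = y0[2],
               d1_mean = y1[1], d1_sd = y1[2],
               d2_mean = y2[1], d2_sd = y2[2],
               d3_mean = y3[1], d3_sd = y3[2],
               stringsAsFactors = FALSE)
  }
  ## For counts the per-year columns are that year's marginal mean/SD
  ## (not change moments); draws are independent across years.
  counts <- rbind(
    cnt("inpatient_admissions",  c(0.5, 0.9),   c(0.3, 0.8),    c(0.2, 0.8),    c(0.2, 0.6)),
    cnt("total_er_visits",       c(1.2, 1.9),   c(0.88, 1.6),   c(0.71, 1.5),   c(0.59, 1.3)),
    cnt("er_physical_visits",    c(0.98, 1.6),  c(0.73, 1.4),   c(0.56, 1.5),   c(0.41, 1.1)),
    cnt("er_mental_visits",      c(0.21, 0.82), c(0.12, 0.49),  c(0.07, 0.44),  c(0.05, 0.33)),
    cnt("er_drug_visits",        c(0.03, 0.26), c(0.01, 0.12),  c(0.005, 0.07), c(0.003, 0.06)),
    cnt("er_alcohol_visits",     c(0.02, 0.204), c(0.012, 0.14), c(0.008, 0.126), c(0.004, 0.071)),
    cnt("admit_after_alcohol_er", c(0.012, 0.141), c(0.004, 0.071), c(0.007, 0.110), c(0.003, 0.052)),
    cnt("admit_after_drug_er",   c(0.014, 0.50), c(0.006, 0.09), c(0.004, 0.07), c(0.002, 0.04)),
    cnt("admit_after_mental_er", c(0.12, 0.50), c(0.068, 0.36), c(0.038, 0.28), c(0.025, 0.24)),
    cnt("admit_after_physical_er", c(0.23, 0.66), c(0.16, 0.56), c(0.14, 0.56), c(0.11, 0.50)),
    cnt("admit_after_other_er",  c(0.02, 0.16), c(0.02, 0.19),  c(0.02, 0.19),  c(0.01, 0.13)),
    cnt("er_other_visits",       c(0.08, 0.94), c(0.09, 0.38),  c(0.05, 0.39),  c(0.05, 0.28)),
    cnt("total_inpatient_nights", c(1.9, 6.6),  c(1.0, 4.2),    c(1.0, 4.7),    c(0.9, 3.8)),
    cnt("hosp_stays_drug",       c(0.005, 0.08), c(0.003, 0.07), c(0.002, 0.04), c(0.002, 0.05)),
    cnt("hosp_stays_mental",     c(0.04, 0.25), c(0.03, 0.19),  c(0.02, 0.14),  c(0.01, 0.12)),
    cnt("hosp_stays_physical",   c(0.09, 0.38), c(0.06, 0.28),  c(0.05, 0.27),  c(0.04, 0.21)),
    cnt("hosp_stays_other",      c(0.02, 0.12), c(0.01, 0.12),  c(0.01, 0.11),  c(0.01, 0.10)),
    cnt("outpatient_mental_routine", c(2.2, 4.6), c(5.5, 9.7),  c(4.0, 8.5),    c(3.3, 7.8)),
    cnt("self_help_visits",      c(0.66, 2.9),  c(1.3, 5.5),    c(0.93, 4.8),   c(0.66, 4.5)),
    cnt("public_clinic_visits",  c(0.21, 1.1),  c(0.48, 2.1),   c(0.29, 1.2),   c(0.26, 1.3)),
    cnt("private_physician_visits", c(0.75, 1.8), c(1.8, 3.2),  c(1.4, 2.7),    c(1.2, 2.7)),
    cnt("outpatient_psychiatric", c(0.55, 1.5), c(1.4, 2.7),    c(1.0, 2.1),    c(0.87, 2.1)),
    cnt("outpatient_other_mental", c(0.82, 2.1), c(2.3, 4.8),   c(1.8, 4.6),    c(1.6, 4.2)),
    cnt("outpatient_other_prof", c(0.18, 1.2),  c(0.43, 1.7),   c(0.21, 0.92),  c(0.14, 0.71)),
    cnt("other_outpatient_visits", c(0.13, 0.92), c(0.30, 1.4), c(0.24, 1.6),   c(0.24, 1.4))
  )
  out <- rbind(score, counts)
  if (subset == "core")
    out <- out[out$variable %in% c("csi", "bmi", "dast", "audit",
                                   "total_er_visits", "er_mental_visits",
                                   "total_inpatient_nights",
                                   "outpatient_mental_routine"), ]
  rownames(out) <- NULL
  out
}

demographic_defaults <- function() {
  list(
    age_mean = 38, age_sd = 8, age_range = c(18, 49),
    p_baseline_working = 0.12,
    p_worked_past_2yr = 0.50,
    education_levels = c("less_hs", "hs", "some_college", "bachelor"),
    education_probs = c(0.20, 0.35, 0.30, 0.15),
    race_levels = c("white", "black", "hispanic", "other"),
    race_probs = c(0.50, 0.25, 0.15, 0.10),
    p_stable_housing = 0.75,
    p_vehicle_access = 0.50
  )
}

## True standardized effects used by the outcome mechanism. Qualitative
## ordering follows the strongest reported predictors: baseline working
## status first, then change in Communication & Cognition, Drive-score
## presence, change in Upper Body Function, work history / education /
## treatment-arm effects, with mental-health ER use as a negative effect.
outcome_defaults <- function() {
  list(
    target_rate = c(y1 = 0.155, y2 = 0.192, y3 = 0.173),
    beta = c(
      baseline_working       = 0.90,
      d_comm_cognition       = 0.35,
      has_drive              = 0.30,
      d_upper_body           = 0.25,
      race_other             = 0.20,
      edu_bachelor           = 0.20,
      worked_past_2yr        = 0.20,
      arm_full               = 0.15,
      arm_basic              = 0.15,
      upper_body             = 0.15,
      d_bmi                  = 0.12,
      er_mental_visits       = -0.15
    )
  )
}

#' Configuration for a synthetic steady-work cohort
#'
#' Assembles and validates the full parameterization of the cohort
#' generator: sample size, study length, arm allocation, per-scale
#' functional-score moments (baseline mean/SD plus per-year
#' change-from-baseline mean/SD), medical-variable moments, the
#' participant-level missing-measurement pattern weights over
#' \{0, 7, 14, 21\} blanked scale scores, the marginal missingness of the
#' Community Mobility Driving/Transit scores, and the logistic outcome
#' mechanism on the standardized design scale.
#'
#' @param n_participants number of participants (default 2944).
#' @param n_years study years including baseline (default 4).
#' @param arm_probabilities allocation probabilities over the full-service,
#'   basic-service and usual-service arms; must sum to 1.
#' @param scale_params data frame of functional-scale moments in the layout
#'   of `fabwork:::fab_scale_defaults()`.
#' @param medical_params data frame of medical-variable moments in the
#'   layout of `fabwork:::medical_defaults()`.
#' @param missingness_params list with `pattern_weights` (probabilities over
#'   0/7/14/21 missing measurements), `p_missing_drive`, `p_missing_transit`
#'   and `p_has_wheelchair`.
#' @param demographic_params list of demographic marginals; see
#'   `fabwork:::demographic_defaults()`.
#' @param outcome_params list with `beta` (named true standardized
#'   coefficients) and either `alpha` (per-year intercepts) or
#'   `target_rate` (per-year steady-work rates to calibrate intercepts to).
#' @param seed integer seed controlling all generator randomness.
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_participants = 200, seed = 1)
#' panel <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_participants = 2944,
                          n_years = 4,
                          arm_probabilities = c(full = 1/3, basic = 1/3, usual = 1/3),
                          scale_params = fab_scale_defaults(),
                          medical_params = medical_defaults(),
                          missingness_params = list(
                            pattern_weights = c(p0 = 0.55, p7 = 0.20,
                                                p14 = 0.15, p21 = 0.10),
                            p_missing_drive = 0.60,
                            p_missing_transit = 0.80,
                            p_has_wheelchair = 0.03),
                          demographic_params = demographic_defaults(),
                          outcome_params = outcome_defaults(),
                          seed = 1L) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      n_participants < 1 || n_participants != round(n_participants))
    stop_cfg("n_participants", "must be a positive integer")
  if (!is.numeric(n_years) || n_years < 2 || n_years != round(n_years))
    stop_cfg("n_years", "must be an integer >= 2")
  if (length(arm_probabilities) != 3 || any(arm_probabilities < 0) ||
      abs(sum(arm_probabilities) - 1) > 1e-9)
    stop_cfg("arm_probabilities", "must be a 3-vector of probabilities summing to 1")
  need <- c("scale", "base_mean", "base_sd")
  if (!all(need %in% names(scale_params)))
    stop_cfg("scale_params", "must contain scale/base_mean/base_sd columns")
  for (t in seq_len(n_years - 1)) {
    for (col in paste0("d", t, c("_mean", "_sd")))
      if (!col %in% names(scale_params))
        stop_cfg("scale_params", sprintf("missing column '%s' for year %d", col, t))
  }
  sd_cols <- grep("_sd$", names(scale_params), value = TRUE)
  if (any(as.matrix(scale_params[sd_cols]) < 0))
    stop_cfg("scale_params", "SDs must be non-negative")
  if (any(scale_params$base_sd <= 0))
    stop_cfg("scale_params", "baseline SDs must be strictly positive")
  if (any(as.matrix(medical_params[grep("_sd$", names(medical_params))]) < 0))
    stop_cfg("medical_params", "SDs must be non-negative")
  w <- missingness_params$pattern_weights
  if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop_cfg("missingness_params$pattern_weights",
             "must be 4 probabilities over {0,7,14,21} summing to 1")
  for (f in c("p_missing_drive", "p_missing_transit", "p_has_wheelchair")) {
    p <- missingness_params[[f]]
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_cfg(paste0("missingness_params$", f), "must be a probability in [0,1]")
  }
  if (is.null(outcome_params$beta) || is.null(names(outcome_params$beta)))
    stop_cfg("outcome_params$beta", "must be a named numeric vector")
  if (is.null(outcome_params$alpha) && is.null(outcome_params$target_rate))
    stop_cfg("outcome_params", "needs either 'alpha' or 'target_rate'")

  structure(list(
    n_participants = as.integer(n_participants),
    n_years = as.integer(n_years),
    arm_probabilities = arm_probabilities,
    scale_params = scale_params,
    medical_params = medical_params,
    missingness_params = missingness_params,
    demographic_params = demographic_params,
    outcome_params = outcome_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic steady-work cohort configuration\n")
  cat(sprintf("  participants: %d, study years: %d (baseline + %d follow-ups)\n",
              x$n_participants, x$n_years, x$n_years - 1))
  cat(sprintf("  functional scales: %d, medical variables: %d\n",
              nrow(x$scale_params), nrow(x$medical_params)))
  w <- x$missingness_params$pattern_weights
  cat(sprintf("  missing-pattern weights (0/7/14/21): %s\n",
              paste(format(w, digits = 3), collapse = " / ")))
  cat(sprintf("  Driving / Transit score missingness: %.0f%% / %.0f%%\n",
              100 * x$missingness_params$p_missing_drive,
              100 * x$missingness_params$p_missing_transit))
  if (!is.null(x$outcome_params$target_rate))
    cat(sprintf("  target steady-work rates by year: %s\n",
                paste(format(x$outcome_params$target_rate), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
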