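#' Sample functional-score trajectories
#'
#' Draws per-participant trajectories of the seven modelled functional
#' scales. The baseline score is normal with the configured scale-specific
#' mean/SD; each post-baseline year adds an independent change draw with
#' that year's change mean/SD, so within-participant correlation across
#' years arises from the shared baseline.
#'
#' @param config a [cohort_config()].
#' @param n number of participants to draw (uses the current RNG state;
#'   seed handling lives in [generate_cohort()]).
#' @return numeric array `[n, n_years, n_scales]` with dimnames on scale.
#' @export
sample_fab_trajectory <- function(config, n = 1L) {
  sp <- config$scale_params
  K <- nrow(sp)
  Tn <- config$n_years
  out <- array(NA_real_, c(n, Tn, K),
               dimnames = list(NULL, paste0("year", 0:(Tn - 1)), sp$scale))
  for (k in seq_len(K)) {
    base <- rnorm(n, sp$base_mean[k], sp$base_sd[k])
    out[, 1, k] <- base
    for (t in seq_len(Tn - 1)) {
      dm <- sp[[paste0("d", t, "_mean")]][k]
      ds <- sp[[paste0("d", t, "_sd")]][k]
      out[, t + 1, k] <- base + rnorm(n, dm, ds)
    }
  }
  out
}

#' Sample medical-variable trajectories
#'
#' Score-type variables (CSI, BMI, DAST, AUDIT) follow a baseline + change
#' trajectory: the baseline is a zero-truncated normal whose location and
#' scale are moment-matched so the realized mean/SD equal the configured
#' targets, and post-baseline years add a normal change draw (floored at
#' zero). Count-type variables are drawn independently per year from a
#' negative binomial matched to that year's mean/SD, falling back to
#' Poisson with a warning when the target variance does not exceed the
#' mean.
#'
#' @inheritParams sample_fab_trajectory
#' @return numeric array `[n, n_years, n_variables]`.
#' @export
sample_medical_counts <- function(config, n = 1L) {
  mp <- config$medical_params
  Tn <- config$n_years
  out <- array(NA_real_, c(n, Tn, nrow(mp)),
               dimnames = list(NULL, paste0("year", 0:(Tn - 1)), mp$variable))
  warned <- FALSE
  for (j in seq_len(nrow(mp))) {
    if (mp$type[j] == "score") {
      ## A zero-truncated normal cannot have mean < ~1.07 SD; for such
      ## over-dispersed scores (DAST, AUDIT) the baseline falls back to a
      ## moment-matched negative binomial, keeping the mean/SD targets.
      if (mp$base_mean[j] / mp$base_sd[j] >= 1.2) {
        par <- truncnorm_match(mp$base_mean[j], mp$base_sd[j])
        base <- rtruncnorm0(n, par$mu, par$sigma)
      } else {
        base <- rcount_match(n, mp$base_mean[j], mp$base_sd[j], warn = FALSE)
      }
      out[, 1, j] <- base
      for (t in seq_len(Tn - 1)) {
        dm <- mp[[paste0("d", t, "_mean")]][j]
        ds <- mp[[paste0("d", t, "_sd")]][j]
        out[, t + 1, j] <- pmax(base + rnorm(n, dm, ds), 0)
      }
    } else {
      for (t in 0:(Tn - 1)) {
        m <- if (t == 0) mp$base_mean[j] else mp[[paste0("d", t, "_mean")]][j]
        s <- if (t == 0) mp$base_sd[j] else mp[[paste0("d", t, "_sd")]][j]
        v <- rcount_match(n, m, s, warn = !warned)
        if (s^2 <= m && m > 0) warned <- TRUE
        out[, t + 1, j] <- v
      }
    }
  }
  out
}

sample_demographics <- function(config, n) {
  dp <- config$demographic_params
  age <- pmin(pmax(rnorm(n, dp$age_mean, dp$age_sd), dp$age_range[1]),
              dp$age_range[2])
  data.frame(
    age = age,
    baseline_working = rbinom(n, 1, dp$p_baseline_working),
    worked_past_2yr = rbinom(n, 1, dp$p_worked_past_2yr),
    education = sample(dp$education_levels, n, TRUE, dp$education_probs),
    race = sample(dp$race_levels, n, TRUE, dp$race_probs),
    stable_housing = rbinom(n, 1, dp$p_stable_housing),
    vehicle_access = rbinom(n, 1, dp$p_vehicle_access),
    arm = sample(names(config$arm_probabilities) %||% c("full", "basic", "usual"),
                 n, TRUE, config$arm_probabilities),
    stringsAsFactors = FALSE
  )
}

## One-hot demographic encoding shared by the truth design and the analysis
## design (reference levels: less_hs education, white race, usual arm).
demographic_dummies <- function(demo) {
  cbind(
    age = demo$age,
    baseline_working = demo$baseline_working,
    worked_past_2yr = demo$worked_past_2yr,
    edu_hs = as.numeric(demo$education == "hs"),
    edu_some_college = as.numeric(demo$education == "some_college"),
    edu_bachelor = as.numeric(demo$education == "bachelor"),
    race_black = as.numeric(demo$race == "black"),
    race_hispanic = as.numeric(demo$race == "hispanic"),
    race_other = as.numeric(demo$race == "other"),
    stable_housing = demo$stable_housing,
    vehicle_access = demo$vehicle_access,
    arm_full = as.numeric(demo$arm == "full"),
    arm_basic = as.numeric(demo$arm == "basic")
  )
}

## Population-moment standardized design over post-baseline person-years,
## built from the truth channel (pre-missingness values). Binary columns
## enter as 0/1. Used only by the outcome mechanism; the analysis design is
## standardized empirically in fit_standardizer()/build_design().
truth_design <- function(panel, config) {
  d <- panel$data
  post <- d$year > 0
  sp <- config$scale_params
  mp <- config$medical_params
  fab_truth <- panel$truth
  n_row <- sum(post)
  year <- d$year[post]

  cols <- list()
  demo <- demographic_dummies(d[post, , drop = FALSE])
  dp <- config$demographic_params
  demo[, "age"] <- (demo[, "age"] - dp$age_mean) / dp$age_sd
  cols$demo <- demo

  base_idx <- match(d$participant[post], d$participant[d$year == 0])
  fb <- fab_truth[d$year == 0, , drop = FALSE][base_idx, , drop = FALSE]
  fy <- fab_truth[post, , drop = FALSE]
  zb <- sweep(sweep(fb, 2, sp$base_mean), 2, sp$base_sd, "/")
  zd <- matrix(NA_real_, n_row, nrow(sp),
               dimnames = list(NULL, paste0("d_", sp$scale)))
  for (k in seq_len(nrow(sp))) {
    dm <- sapply(year, function(t) sp[[paste0("d", t, "_mean")]][k])
    ds <- sapply(year, function(t) sp[[paste0("d", t, "_sd")]][k])
    zd[, k] <- (fy[, k] - fb[, k] - dm) / ds
  }
  colnames(zb) <- sp$scale
  cols$fab <- cbind(zb, zd)
  cols$presence <- as.matrix(d[post, c("has_drive", "has_ride", "has_wheelchair")])

  med_names <- mp$variable
  mb <- as.matrix(d[d$year == 0, med_names, drop = FALSE])[base_idx, , drop = FALSE]
  my <- as.matrix(d[post, med_names, drop = FALSE])
  zmb <- sweep(sweep(mb, 2, mp$base_mean), 2, mp$base_sd, "/")
  zmd <- matrix(NA_real_, n_row, nrow(mp),
                dimnames = list(NULL, paste0("d_", med_names)))
  for (j in seq_len(nrow(mp))) {
    mt <- sapply(year, function(t) mp[[paste0("d", t, "_mean")]][j])
    st <- sapply(year, function(t) mp[[paste0("d", t, "_sd")]][j])
    if (mp$type[j] == "score") {
      zmd[, j] <- (my[, j] - mb[, j] - mt) / st
    } else {
      ## counts drawn independently per year: population change moments
      zmd[, j] <- (my[, j] - mb[, j] - (mt - mp$base_mean[j])) /
        sqrt(st^2 + mp$base_sd[j]^2)
    }
  }
  colnames(zmb) <- med_names
  cols$med <- cbind(zmb, zmd)

  list(z = do.call(cbind, cols), year = year, row = which(post))
}

#' Draw steady-work outcomes from the logistic mechanism
#'
#' Generates `y ~ Bernoulli(inv_logit(alpha[year] + z' beta))` independently
#' across person-years. `beta` is named on design columns; names absent
#' from the design raise an error.
#'
#' @param z standardized design matrix (one row per post-baseline
#'   person-year) with column names.
#' @param year integer vector of study years (1-based post-baseline).
#' @param outcome_params list with named `beta` and per-year `alpha`.
#' @return integer 0/1 vector of outcomes.
#' @export
sample_outcome <- function(z, year, outcome_params) {
  beta <- outcome_params$beta
  missing_cols <- setdiff(names(beta), colnames(z))
  if (length(missing_cols))
    stop("outcome coefficients name columns absent from the design: ",
         paste(missing_cols, collapse = ", "))
  alpha <- outcome_params$alpha
  if (is.null(alpha)) stop("outcome_params$alpha missing; calibrate first")
  if (length(alpha) == 1) alpha <- rep(alpha, max(year))
  eta <- alpha[year] + as.vector(z[, names(beta), drop = FALSE] %*% beta)
  rbinom(length(eta), 1, inv_logit(eta))
}

## Solve the per-year intercepts so the mean generated probability equals
## the target year-specific steady-work rate.
calibrate_intercepts <- function(eta_no_alpha, year, target_rate) {
  vapply(seq_along(target_rate), function(t) {
    e <- eta_no_alpha[year == t]
    uniroot(function(a) mean(inv_logit(a + e)) - target_rate[t],
            c(-15, 15), tol = 1e-10)$root
  }, numeric(1))
}

#' Generate a synthetic steady-work cohort
#'
#' Produces a long-format person-year panel with the moment structure of a
#' supported-employment trial cohort: functional-scale trajectories,
#' medical/utilization trajectories, baseline demographics, participant
#' level missing-measurement patterns over \{0, 7, 14, 21\} blanked scale
#' scores, Bernoulli presence of the Community Mobility Driving/Transit
#' scores, and a steady-work outcome drawn from a logistic mechanism on the
#' standardized truth design with intercepts calibrated to the configured
#' per-year rates.
#'
#' @param config a [cohort_config()].
#' @return an object of class `sw_panel`: a list with `data` (one row per
#'   person-year; masked functional scores are `NA`), `mask` (logical
#'   matrix, person-year rows by scale, `TRUE` = blanked), `truth` (the
#'   pre-missingness functional scores), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  Tn <- config$n_years
  sp <- config$scale_params

  demo <- sample_demographics(config, n)
  fab <- sample_fab_trajectory(config, n)
  med <- sample_medical_counts(config, n)

  idx <- rep(seq_len(n), each = Tn)
  year <- rep.int(0:(Tn - 1), n)
  d <- data.frame(participant = idx, year = year)
  d <- cbind(d, demo[idx, , drop = FALSE])
  rownames(d) <- NULL
  fab_long <- matrix(NA_real_, n * Tn, nrow(sp), dimnames = list(NULL, sp$scale))
  med_long <- matrix(NA_real_, n * Tn, dim(med)[3],
                     dimnames = list(NULL, dimnames(med)[[3]]))
  for (t in 0:(Tn - 1)) {
    fab_long[year == t, ] <- fab[, t + 1, ]
    med_long[year == t, ] <- med[, t + 1, ]
  }
  d <- cbind(d, fab_long, med_long)
  d$steady_work <- NA_integer_

  panel <- structure(list(data = d,
                          mask = matrix(FALSE, nrow(d), nrow(sp),
                                        dimnames = list(NULL, sp$scale)),
                          truth = fab_long,
                          config = config),
                     class = "sw_panel")
  panel <- apply_missingness(panel, config)

  td <- truth_design(panel, config)
  op <- config$outcome_params
  if (is.null(op$alpha)) {
    beta <- op$beta
    eta0 <- as.vector(td$z[, names(beta), drop = FALSE] %*% beta)
    op$alpha <- calibrate_intercepts(eta0, td$year, op$target_rate)
  }
  y <- sample_outcome(td$z, td$year, op)
  panel$data$steady_work[td$row] <- y
  panel$outcome_alpha <- op$alpha
  panel
}

#' Impose the study's missing-measurement structure on a panel
#'
#' Each participant is assigned a pattern from \{0, 7, 14, 21\} missing
#' functional measurements: a pattern of `7k` blanks all seven scale scores
#' in `k` randomly chosen post-baseline assessment waves. Pre-missingness
#' values are retained in the panel's truth channel. Presence of the
#' Community Mobility Driving and Transit scores is drawn Bernoulli per
#' person-year at the configured marginal rates, as is wheelchair-score
#' presence.
#'
#' @param panel an `sw_panel` with fully observed functional scores.
#' @param config a [cohort_config()].
#' @return the panel with `mask` set, masked cells `NA` in `data`, and
#'   `has_drive`/`has_ride`/`has_wheelchair` columns added.
#' @export
apply_missingness <- function(panel, config) {
  stopifnot(inherits(panel, "sw_panel"))
  mp <- config$missingness_params
  w <- mp$pattern_weights
  if (abs(sum(w) - 1) > 1e-9)
    stop_cfg("missingness_params$pattern_weights", "must sum to 1")
  d <- panel$data
  n <- config$n_participants
  Tn <- config$n_years
  K <- ncol(panel$mask)

  n_waves <- sample(0:3, n, TRUE, prob = w)
  mask <- panel$mask
  post_years <- seq_len(Tn - 1)
  for (i in which(n_waves > 0)) {
    waves <- sample(post_years, n_waves[i])
    rows <- which(d$participant == i & d$year %in% waves)
    mask[rows, ] <- TRUE
  }
  d[, colnames(mask)][mask] <- NA_real_

  d$has_drive <- rbinom(nrow(d), 1, 1 - mp$p_missing_drive)
  d$has_ride <- rbinom(nrow(d), 1, 1 - mp$p_missing_transit)
  d$has_wheelchair <- rbinom(nrow(d), 1, mp$p_has_wheelchair)

  panel$data <- d
  panel$mask <- mask
  panel
}

#' Restore the pre-missingness panel from the truth channel
#'
#' @param panel an `sw_panel`.
#' @return the panel with all masked functional scores restored and the
#'   mask cleared.
#' @export
unmask_panel <- function(panel) {
  stopifnot(inherits(panel, "sw_panel"))
  panel$data[, colnames(panel$mask)] <- panel$truth
  panel$mask[] <- FALSE
  panel
}

#' @export
print.sw_panel <- function(x, ...) {
  d <- x$data
  post <- d$year > 0
  cat(sprintf("Synthetic steady-work panel: %d participants x %d years (%d rows)\n",
              length(unique(d$participant)), length(unique(d$year)), nrow(d)))
  cat(sprintf("  post-baseline steady-work rate: %.3f\n",
              mean(d$steady_work[post])))
  cat(sprintf("  blanked scale-score cells: %d (%.1f%% of scale cells)\n",
              sum(x$mask), 100 * mean(x$mask)))
  cat(sprintf("  Driving / Transit score present: %.2f / %.2f\n",
              mean(d$has_drive), mean(d$has_ride)))
  invisible(x)
}

#' Count missing functional measurements per participant
#'
#' Counts blanked non-Community-Mobility scale scores, the quantity the
#' missingness-tolerance filter thresholds on.
#'
#' @param panel an `sw_panel`.
#' @return named integer vector over participants.
#' @export
missing_measurements <- function(panel) {
  tapply(rowSums(panel$mask), panel$data$participant, sum)
}

#' Write a panel to plain-text files
#'
#' Writes `<stem>.csv` (person-year rows, missing cells empty),
#' `<stem>_mask.csv`, `<stem>_truth.csv` and `<stem>_config.json`.
#'
#' @param panel an `sw_panel`.
#' @param stem path stem (without extension).
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, stem) {
  paths <- c(data = paste0(stem, ".csv"),
             mask = paste0(stem, "_mask.csv"),
             truth = paste0(stem, "_truth.csv"),
             config = paste0(stem, "_config.json"))
  utils::write.csv(panel$data, paths["data"], row.names = FALSE, na = "")
  utils::write.csv(panel$mask, paths["mask"], row.names = FALSE)
  utils::write.csv(panel$truth, paths["truth"], row.names = FALSE)
  cfg <- unclass(panel$config)
  cfg$arm_probabilities <- as.list(cfg$arm_probabilities)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

#' Read a panel written by [write_panel()]
#'
#' @param stem path stem used when writing.
#' @return an `sw_panel`.
#' @export
read_panel <- function(stem) {
  d <- utils::read.csv(paste0(stem, ".csv"))
  mask <- as.matrix(utils::read.csv(paste0(stem, "_mask.csv"))) == TRUE
  truth <- as.matrix(utils::read.csv(paste0(stem, "_truth.csv")))
  cfg <- jsonlite::read_json(paste0(stem, "_config.json"), simplifyVector = TRUE)
  structure(list(data = d, mask = mask, truth = truth, config = cfg),
            class = "sw_panel")
}
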