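## Shared fixtures: designs and reduced-scale cohort configurations built
## in code at test time.

## A bare design matrix wrapped as sw_design, bypassing the generator.
small_design <- function(n = 60, p = 1, beta = rep(0.8, p), alpha = -0.4,
                         seed = 1, mask_cells = NULL, classes = "medical",
                         years = 1L) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  y <- rbinom(n, 1, inv_logit(alpha + as.vector(z %*% beta)))
  mask <- matrix(FALSE, n, p, dimnames = dimnames(z))
  if (!is.null(mask_cells)) {
    mask[mask_cells] <- TRUE
    z[mask] <- NA
  }
  structure(list(
    y = y, z = z, mask = mask,
    info = data.frame(name = colnames(z),
                      class = rep_len(classes, p),
                      kind = "baseline", stringsAsFactors = FALSE),
    year = rep_len(seq_len(years), n),
    participant = seq_len(n)
  ), class = "sw_design")
}

## Fast sampler settings for unit tests.
quick_spec <- function(seed = 1, draws = 400, warmup = 300, chains = 1, ...) {
  logistic_spec(learn_shrinkage = FALSE, year_effect = FALSE,
                chains = chains, draws = draws, warmup = warmup,
                seed = seed, ...)
}

## Reduced-scale cohort: core medical variables, optional missingness off,
## configurable true effects on the standardized design scale.
test_cohort_config <- function(n = 500, seed = 1,
                               beta = c(baseline_working = 0.9,
                                        worked_past_2yr = 0.2,
                                        race_other = 0.2,
                                        edu_bachelor = 0.2,
                                        arm_full = 0.15, arm_basic = 0.15),
                               missing_patterns = c(1, 0, 0, 0)) {
  cohort_config(
    n_participants = n, seed = seed,
    medical_params = fabwork:::medical_defaults("core"),
    missingness_params = list(pattern_weights = missing_patterns,
                              p_missing_drive = 0.60,
                              p_missing_transit = 0.80,
                              p_has_wheelchair = 0.03),
    outcome_params = list(target_rate = c(y1 = 0.155, y2 = 0.192, y3 = 0.173),
                          beta = beta))
}

## Assemble an sw_fit of the linear family from explicit draws, for
## testing summary operations with hand-set posteriors.
manual_linear_fit <- function(draws_alpha, draws_beta, design,
                              spec = quick_spec()) {
  draws <- cbind(draws_alpha, draws_beta)
  layout <- list(idx = list(alpha = 1L, beta = 1L + seq_len(ncol(design$z))),
                 p = ncol(design$z), years = sort(unique(design$year)),
                 cells = which(design$mask, arr.ind = TRUE),
                 miss_cols = integer(0), cell_group = integer(0))
  structure(list(draws = draws, layout = layout, design = design,
                 spec = spec, diagnostics = list(algorithm = "manual"),
                 type = "logistic"),
            class = c("sw_logistic", "sw_fit"))
}
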