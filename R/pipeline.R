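#' Run the full simulate / prepare / fit / evaluate pipeline
#'
#' Orchestrates cohort generation, missingness-tolerance filtering, design
#' construction per covariate submodel, model fitting per requested
#' family, PSIS-LOO evaluation, and model comparison, writing every
#' artifact as CSV/JSON under `out_dir` and recording all paths and seeds
#' in a manifest.
#'
#' @param config list (or path to a JSON file) with any of:
#'   `n_participants`, `seed`, `tolerance` (default 14),
#'   `covariate_sets` (subset of demo/demo+fab/demo+med/full),
#'   `models` (subset of glm/piecewise/bnn), `draws`, `warmup`, `chains`,
#'   `algorithm`, `out_dir`.
#' @return the manifest (invisibly written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    n_participants = 2944, seed = 1L, tolerance = 14,
    covariate_sets = c("demo", "demo+fab", "demo+med", "full"),
    models = "glm", draws = 1000, warmup = 500, chains = 4,
    algorithm = "hmc", medical = "all", out_dir = "fabwork_run"
  ), config)
  bad <- setdiff(cfg$covariate_sets, c("demo", "demo+fab", "demo+med", "full"))
  if (length(bad)) stop("unknown covariate sets: ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, artifacts = list(), stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  panel <- stage("simulate", {
    ## `medical = "core"` trims the ultra-rare utilization counts, which
    ## are degenerate (all-zero, hence unstandardizable) in small cohorts
    cc <- cohort_config(n_participants = cfg$n_participants, seed = cfg$seed,
                        medical_params = medical_defaults(cfg$medical))
    generate_cohort(cc)
  })
  stem <- file.path(cfg$out_dir, "panel")
  manifest$artifacts$panel <- as.list(write_panel(panel, stem))
  manifest$stages$simulate <- list(seed = cfg$seed,
                                   n = cfg$n_participants)

  prep <- stage("prep", {
    flt <- filter_by_missingness(panel, cfg$tolerance)
    params <- fit_standardizer(flt)
    list(panel = flt, params = params)
  })
  std_path <- file.path(cfg$out_dir, "standardizer.csv")
  utils::write.csv(prep$params, std_path, row.names = FALSE)
  manifest$artifacts$standardizer <- std_path
  manifest$stages$prep <- list(tolerance = cfg$tolerance,
                               retained = length(unique(prep$panel$data$participant)))

  evals <- list()
  for (cs in cfg$covariate_sets) {
    design <- stage(paste0("design:", cs),
                    build_design(prep$panel, prep$params, cs))
    for (mdl in cfg$models) {
      key <- paste(mdl, cs, sep = ":")
      seed_fit <- derive_seed(cfg$seed, length(evals) + 1)
      fit <- stage(paste0("fit:", key), {
        sp <- logistic_spec(covariate_set = cs, algorithm = cfg$algorithm,
                            draws = cfg$draws, warmup = cfg$warmup,
                            chains = cfg$chains, seed = seed_fit)
        switch(mdl,
               glm = fit_logistic(design, sp),
               piecewise = fit_piecewise_glm(design, spec = sp),
               bnn = fit_bnn(design, bnn_spec(draws = cfg$draws,
                                              seed = seed_fit)),
               stop("unknown model '", mdl, "'"))
      })
      dir_m <- file.path(cfg$out_dir, gsub("[^a-z+]", "_", key))
      dir.create(dir_m, showWarnings = FALSE)
      draws_path <- file.path(dir_m, "draws.csv")
      utils::write.csv(fit$draws, draws_path, row.names = FALSE)
      if (inherits(fit, "sw_logistic") || inherits(fit, "sw_piecewise")) {
        or_path <- file.path(dir_m, "odds_ratios.csv")
        utils::write.csv(odds_ratios(fit), or_path, row.names = FALSE)
      } else or_path <- NULL
      ev <- stage(paste0("evaluate:", key), evaluate_model(fit, design, key))
      roc_path <- file.path(dir_m, "roc.csv")
      prc_path <- file.path(dir_m, "prc.csv")
      utils::write.csv(ev$roc$points, roc_path, row.names = FALSE)
      utils::write.csv(ev$prc$points, prc_path, row.names = FALSE)
      jsonlite::write_json(
        list(model = mdl, covariate_set = cs, seed = seed_fit,
             elpd = ev$loo$elpd, elpd_se = ev$loo$se,
             auroc = ev$roc$auc, auprc = ev$prc$auc,
             n_high_k = ev$loo$n_high_k,
             diagnostics = fit$diagnostics),
        file.path(dir_m, "summary.json"), auto_unbox = TRUE, digits = NA)
      manifest$artifacts[[key]] <- c(
        list(draws = draws_path, roc = roc_path, prc = prc_path,
             summary = file.path(dir_m, "summary.json")),
        if (!is.null(or_path)) list(odds_ratios = or_path))
      evals[[key]] <- ev
    }
  }

  cmp <- stage("compare", compare_models(evals))
  cmp_path <- file.path(cfg$out_dir, "comparison.csv")
  utils::write.csv(cmp, cmp_path, row.names = FALSE)
  manifest$artifacts$comparison <- cmp_path

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  manifest$path <- manifest_path
  invisible(manifest)
}

#' Render report tables from a pipeline run
#'
#' Produces the headline report surfaces: a top-k odds-ratio table per
#' linear-family model (default k = 32), per-covariate-set top-10 tables,
#' and the model-comparison table, all read back from the run's artifact
#' files without recomputation.
#'
#' @param manifest a manifest from [run_pipeline()] or the path to one.
#' @param top_k rows in the headline odds-ratio table.
#' @return list of data frames; also written as CSV next to the manifest.
#' @export
render_report <- function(manifest, top_k = 32) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  out_dir <- manifest$config$out_dir
  arts <- manifest$artifacts
  report <- list()
  for (key in names(arts)) {
    a <- arts[[key]]
    if (is.list(a) && !is.null(a$odds_ratios)) {
      if (!file.exists(a$odds_ratios))
        stop("missing artifact: ", a$odds_ratios)
      or <- utils::read.csv(a$odds_ratios)
      report[[paste0("top_", key)]] <- utils::head(or, top_k)
      report[[paste0("top10_", key)]] <- utils::head(or, 10)
    }
  }
  if (!file.exists(arts$comparison)) stop("missing artifact: ", arts$comparison)
  report$comparison <- utils::read.csv(arts$comparison)
  for (nm in names(report)) {
    utils::write.csv(report[[nm]],
                     file.path(out_dir, paste0("report_", gsub("[^a-z0-9_+]", "_", nm), ".csv")),
                     row.names = FALSE)
  }
  report
}
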