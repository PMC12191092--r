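# fabwork

Does *functional* improvement predict a return to steady work better than
*medical* improvement? For people with mental health conditions moving
through supported-employment programs, disability adjudication still
leans on medical impairment and health-care utilization records, while
multidimensional self-reported function — e.g. the Work Disability
Functional Assessment Battery (WD-FAB), with scales for basic mobility,
upper-body and fine-motor function, communication & cognition,
resilience, interpersonal interactions and mood — may carry more signal
about work capacity. `fabwork` packages the full modelling chain needed
to study that question on longitudinal person-year panels, together with
a calibrated synthetic cohort generator so the whole chain is testable
without access to restricted trial data.

## What is inside

* **Synthetic cohorts** (`cohort_config()`, `generate_cohort()`): a
  2,944-participant, 4-year person-year panel with published-moment
  calibration — per-scale baseline and change-from-baseline means/SDs,
  29 medical/utilization variables, wave-structured missingness in
  {0, 7, 14, 21} measurements per participant, ~60%/~80% missing
  Community Mobility Driving/Transit scores (consumed as presence
  indicators), and a steady-work outcome from a logistic mechanism with
  per-year rates calibrated to 0.155 / 0.192 / 0.173.
* **Design preparation** (`compute_changes()`, `fit_standardizer()`,
  `filter_by_missingness()`, `build_design()`): baseline + change
  predictors, standardization on observed cells, missingness-tolerance
  filtering, and the four covariate submodels `demo`, `demo+fab`,
  `demo+med`, `full`.
* **Models**: Bayesian hierarchical logistic regression
  (`fit_logistic()`) where masked covariate cells are latent parameters
  marginalized during inference,

      y_it ~ Bernoulli(inv_logit(alpha + u_t + z_it' beta)),
      beta_j ~ N(0, lambda),  u_t ~ N(0, tau),
      z_miss ~ N(mu_col, sigma_col)  (non-centered),

  a piecewise-linear GLM by additive coefficient decomposition
  (`fit_piecewise_glm()`, `beta_cell = beta_global + sum_d delta_{d,l}`),
  and a shallow Bayesian neural network (`fit_bnn()`, default hidden
  width 12, `width_scan()` over 2–20). Inference is an adaptive HMC
  sampler (or mean-field variational inference) built into the package.
* **Evaluation** (`loo_predictive()`, `roc_curve()`, `pr_curve()`,
  `compare_models()`): Pareto-smoothed importance-sampling leave-one-out
  cross-validation with per-observation elpd and k-hat diagnostics, and
  LOO-cross-validated ROC / precision-recall curves.
* **Orchestration** (`run_pipeline()`, `render_report()`): simulate →
  prepare → fit → evaluate → compare with seeds and a manifest, emitting
  odds-ratio forest tables, curve files and a model-comparison table as
  CSV/JSON.

## Worked example

```r
library(fabwork)

cfg <- cohort_config(n_participants = 600, seed = 42)
panel <- generate_cohort(cfg)
panel
#> Synthetic steady-work panel: 600 participants x 4 years (2400 rows)
#>   post-baseline steady-work rate: 0.161
#>   blanked scale-score cells: 3283 (19.5% of scale cells)
#>   Driving / Transit score present: 0.40 / 0.19

panel14 <- filter_by_missingness(panel, tolerance = 14)
design <- build_design(panel14, fit_standardizer(panel14), "demo+fab")
design
#> Steady-work design: 1623 person-year rows, 30 columns
#>   columns by class: demographic=13, function=17
#>   outcome rate: 0.160; masked cells: 2044 (4.2%)

fit <- fit_logistic(design, logistic_spec(covariate_set = "demo+fab",
                                          chains = 2, draws = 500,
                                          warmup = 400, seed = 7))
summary(fit, top = 5)
#> Bayesian logistic model for steady work
#>   1000 draws, 2094 parameters; design: 1623 rows x 30 columns (demo+fab)
#>   HMC: accept 0.88, divergences 38, max rhat 1.013
#>
#> Top predictors (posterior mean odds ratio, 95% CrI):
#>               name       class      kind    OR    lo    hi
#> 1 baseline_working demographic indicator 1.612 1.117 2.375
#> 2     d_upper_body    function    change 1.261 1.092 1.453
#> 3 d_comm_cognition    function    change 1.221 1.051 1.410
#> 4       upper_body    function  baseline 1.153 1.001 1.327
#> 5     edu_bachelor demographic indicator 0.887 0.654 1.111

evaluate_model(fit, design, label = "glm demo+fab")
#> Model evaluation [glm demo+fab]
#> PSIS-LOO over 1623 observations
#>   elpd_loo: -698.4 (SE 24.6)
#>   Pareto k > 0.7: 0 observation(s)
#> ROC curve: 1624 operating points, AUROC = 0.6112
#> PRC curve: 1623 operating points, AUPRC = 0.2323 (chance level 0.160)
```

Reading the output: the largest effects sit on baseline working status
and on *changes* in Upper Body Function and Communication & Cognition —
functional improvement — with standardized odds ratios around 1.2–1.6 and
95% credible intervals excluding 1. The LOO-cross-validated AUROC of
~0.61 on this deliberately small 600-participant cohort quantifies
out-of-sample discrimination; the PR curve is read against its chance
level (the steady-work prevalence, 0.16). In cohorts generated with true
effects only on function-change columns, the `demo+fab` submodel beats
`demo+med` in LOO-AUROC in ≥ 9 of 10 replicates — the synthetic analogue
of the finding that functional improvement out-predicts medical
improvement.

A full run over all four covariate submodels:

```r
man <- run_pipeline(list(n_participants = 2944, seed = 1, tolerance = 14,
                         covariate_sets = c("demo", "demo+fab",
                                            "demo+med", "full"),
                         models = "glm", out_dir = "run1"))
render_report(man)          # top-32 / top-10 OR tables, comparison table
```

## Package layout

```
R/            generator, design prep, samplers, models, PSIS-LOO, curves,
              pipeline
tests/        testthat suite: unit, property and end-to-end scientific
              checks (oracle comparisons, coverage, headline reproduction)
scripts/      acceptance.R (calibration reproduction)
vignettes/    methods vignette: models, priors, numerical choices,
              generator assumptions and limitations
```
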