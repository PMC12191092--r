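---
title: "Modelling steady work from functional and medical trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling steady work from functional and medical trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Supported-employment trials for people with mental health conditions track
two very different kinds of longitudinal information: *function* —
self-reported multi-scale scores such as the Work Disability Functional
Assessment Battery (WD-FAB), covering mobility, upper-body and fine-motor
function, cognition, resilience, interpersonal interaction and mood — and
*medical* state, mostly health-care utilization counts (ER visits,
inpatient nights, outpatient visits) plus screening scores (Colorado
Symptom Index, BMI, DAST, AUDIT). The question this package is built
around is comparative: which class of information better predicts whether
a participant achieves *steady work* (employment of at least half-time in
a study year)?

The package provides the full analysis chain as reusable, tested
components: a calibrated synthetic cohort generator, design preparation,
three Bayesian model families, and leave-one-out cross-validated
evaluation. Everything runs on synthetic cohorts, because the underlying
trial data are distributed under restricted access; the generator
reproduces the *published statistical structure* of such a cohort so that
every downstream method is exercised under realistic conditions.

## The synthetic cohort generator

`cohort_config()` + `generate_cohort()` produce a long person-year panel
(default 2,944 participants, baseline plus three annual follow-ups).

**Functional scales.** Seven scales are modelled on the WD-FAB T-score
metric. A participant's baseline is normal with scale-specific mean/SD
(e.g. Mood & Emotions 38.6 (12.0), Resilience 47.6 (9.6)); each
post-baseline year adds an independent normal change draw with
year-specific change mean/SD (e.g. Communication & Cognition year-2
change 0.7 (7.0)). Sharing the baseline across years induces the
within-participant correlation; no additional serial structure (e.g.
AR(1) in the changes) is imposed, because only marginal change moments
are published.

**Medical variables.** 29 variables. Screening scores use a
zero-truncated normal whose location and scale are *moment-matched*
numerically, so the realized mean/SD equal the configured targets exactly
in expectation (naive truncation would, for instance, bias the CSI mean
upward by about 0.4 points). Scores whose target mean is smaller than
their SD (DAST, AUDIT) cannot be represented by a zero-truncated normal
at all — its mean/SD ratio is bounded below near 1 — and fall back to a
moment-matched negative binomial baseline. Utilization counts are drawn
independently per year from a negative binomial matched to that year's
mean/SD, with a Poisson fallback (and warning) when the target variance
does not exceed the mean. Medical and functional variables are generated
independently; a cross-variable correlation structure is a configuration
extension we deliberately left out, since no joint moments are published.

**Missingness.** The study's characteristic pattern is participant-level:
scale scores are missing in whole assessment waves, so the per-participant
count of missing non-Community-Mobility measurements is 0, 7, 14 or 21.
`apply_missingness()` draws a pattern per participant (default weights
0.55/0.20/0.15/0.10 — chosen once to match the qualitative statement that
most participants miss 0, 7 or 14 measurements; the published figure is a
plot, not a table) and blanks all seven scales in the chosen post-baseline
waves. Missingness is completely at random given the pattern; informative
missingness is off by default because no mechanism is published. The
Community Mobility Driving and Transit scores are a separate phenomenon:
they are administered only to participants who use those transportation
modes, and are missing for about 60% and 80% of records respectively. The
generator never materializes those scores; it draws per-record *presence
indicators* (40%/20% present, wheelchair 3%), which is also how the models
consume them. Pre-missingness values are retained in a truth channel so
tests can verify bookkeeping exactly.

**Demographics.** Age (normal 38 (8), truncated to the recruitment range
18–49), baseline working status (12%), worked-in-past-2-years (50%),
education and race categories, stable housing, vehicle access, and a
1/3–1/3–1/3 split over the full-service/basic-service/usual-service arms.
These marginals are plausible defaults, config-overridable; no frequency
table is published for them.

**Outcome.** Steady work is Bernoulli in a logistic model on the
*standardized truth design*: `y ~ Bernoulli(inv_logit(alpha_t + z' beta))`.
The default true coefficients load most strongly on baseline working
status, then on changes in Communication & Cognition and Upper Body
Function, Driving-score presence, work history, education and treatment
arm, with mental-health ER visits negative — the qualitative ordering of
the strongest reported predictors. The per-year intercepts `alpha_t` are
calibrated by root-finding so the mean generated probability equals the
year-specific steady-work rates 0.155 / 0.192 / 0.173; given those
targets the only deviation left in a generated cohort is binomial noise.

What passing calibration tests shows — and what it does not: the sample
moments, missingness geometry, prevalence and effect ordering match the
published cohort, but real WD-FAB trajectories have item-level structure,
cross-domain correlation and informative missingness that this generator
does not emulate. Conclusions about *methods* transfer; conclusions about
*the population* do not.

## Design preparation

Each predictor enters the models twice: its baseline value and its
change-from-baseline for the study year (`compute_changes()`; a change is
missing when either side is). `fit_standardizer()` learns observed-cell
means/SDs for baselines and changes — persisted so all covariate
submodels share identical scaling, which is what makes effect sizes
comparable across submodels — and `build_design()` assembles one row per
post-baseline person-year for a covariate set: `demo`, `demo+fab`,
`demo+med` or `full`. Binary indicators and dummies stay 0/1; continuous
columns are standardized. `filter_by_missingness()` retains participants
with at most 0, 7 or 14 missing measurements (the most inclusive
tolerance, 14, is the default in the pipeline). Change covariates are
year-specific rows of one pooled design rather than separate per-year
models; the pooled model carries a year-level random intercept instead.
Counts enter untransformed before standardization (no log transform),
matching the published description, which states none.

## The hierarchical logistic model

For person-year rows,

`y_it ~ Bernoulli(inv_logit(alpha + u_t + z_it' beta))`

with `alpha ~ N(0, 2.5)`, a shared shrinkage prior
`beta_j ~ N(0, lambda)`, `lambda ~ half-N(0, 1)` (switchable to a fixed
scale), and year intercepts `u_t ~ N(0, tau)`, `tau ~ half-N(0, 1)`.
Masked design cells are not imputed once: each masked cell gets a latent
parameter with prior `N(mu_col, sigma_col)` on the standardized scale,
and the latents are sampled jointly with the regression parameters, so
missing covariates are marginalized during inference. The imputation
hyperparameters are learned per column (`mu ~ N(0,1)`,
`sigma ~ half-N(0,1)`) or pinned at (0, 1).

Two numerical choices matter here. First, the latents use a
*non-centered* parameterization (`z = mu + sigma * z_raw`); with
thousands of masked cells the centered form produces a funnel between the
latents and their hyperparameters that stalls the sampler (split-R-hat on
the hyperparameters was ~3.9 centered vs ~1.01 non-centered on a
600-participant cohort). Second, separation is handled entirely by the
shrinkage prior; there is no Firth-style correction.

Inference is an adaptive Hamiltonian Monte Carlo sampler written for the
package: dual-averaging step-size adaptation toward 0.8 acceptance,
diagonal mass matrix re-estimated mid-warmup, jittered trajectory length
of 8–24 leapfrog steps, default 4 chains of 1,000 retained draws after
500 warmup iterations. Convergence is reported (acceptance rate,
divergence count, split-R-hat across chains) and doubtful fits are
flagged with a warning, never silently returned. A mean-field variational
option (`algorithm = "vi"`) exists for speed, with the usual caveat that
it underestimates posterior spread.

Credible intervals everywhere are central 95% intervals with
linear-interpolation empirical quantiles. `odds_ratios()` reports
`mean(exp(beta_j))` with 2.5%/97.5% quantiles, sorted by |posterior mean
log OR| for top-k tables.

One note on the recovery studies in the test suite: frequentist coverage
of credible intervals is checked with the *fixed-scale* prior variant.
Under the hierarchical shrinkage prior a single large coefficient among
many nulls is deliberately biased toward zero (we measured ~0.11 log-OR
shrinkage on a 0.9 coefficient, dropping its coverage to ~0.7); that is
the prior doing its job, not an estimation defect, so nominal-coverage
claims are only meaningful for the unshrunk variant.

## Piecewise-linear GLM by additive decomposition

`fit_piecewise_glm()` represents region-specific coefficients as
`beta_cell = beta_global + sum_d delta_{d, level_d(cell)}`, where each
partition dimension is a design covariate cut at quantile knots (default
terciles; binary columns split on their values) and every deviation —
intercept and slopes — carries a zero-mean `N(0, dev_scale)` shrinkage
prior (default 0.5). No sum-to-zero constraint is imposed; the model is
identified through shrinkage, so tests compare predictions or
`beta_global + mean(delta)`, never raw components. As `dev_scale -> 0`
the model collapses onto the plain logistic fit, which is verified as a
degenerate-limit test. Default partition covariates are baseline
Communication & Cognition and baseline working status — the published
account does not say which covariates define its local regions, so this
is a documented, fully configurable default. Partition covariates must be
fully observed: under hard knots, a latent partition covariate would make
cell membership itself random per draw, which the hard-partition additive
decomposition does not define; the default partition covariates are never
masked in generated cohorts.

## Shallow Bayesian neural network

`fit_bnn()` fits `y ~ Bernoulli(inv_logit(w2' a(W1' z + b1) + b2))` with
one hidden layer (default width 12), tanh activation (smooth, for
gradient-based inference), independent normal priors on all weights, and
the same latent-imputation scheme for masked cells. Default inference is
mean-field variational with reparameterization gradients, Adam, and 5
random restarts keeping the best smoothed ELBO — restarts guard against
mode collapse in the multimodal weight posterior; full HMC is available
via `algorithm = "hmc"`. `width_scan()` refits across widths (default
2–20), scores each by PSIS-LOO elpd, and selects the smallest width
within one standard error of the best.

## PSIS-LOO evaluation

`loo_predictive()` estimates, per observation, the leave-one-out
predictive density and `P(y_i = 1 | data minus i)` from a single fit by
importance sampling with raw log-weights `-loglik[, i]`. The
`M = min(ceil(0.2 S), ceil(3 sqrt(S)))` largest weights are replaced by
expected order statistics of a generalized Pareto distribution fitted to
their exceedances (profile-likelihood estimator with the standard
weakly-informative shape regularization), truncated at the raw maximum
and renormalized. The shape diagnostic k-hat is reported per observation
and every report surfaces the count above 0.7. Fewer than 25 draws falls
back to truncated importance sampling; fewer than 5 exceedances skips
smoothing. Against exact refit leave-one-out (computed by dense grid
integration on a 40-observation logistic fit with 4,000 draws) the
pointwise elpd agrees to well under 0.01.

ROC and precision-recall curves are built from the LOO predictive
probabilities. Ties are grouped (equal scores cross a threshold
together), the AUROC is trapezoidal — hence exactly the Mann-Whitney
`U/(n1 n0)` statistic — and the AUPRC uses step-wise (right-continuous)
interpolation, because linear interpolation is biased for PR curves; the
prevalence baseline is recorded with every PR curve. The LOO unit is the
person-year observation, not the participant; participant-level grouping
would be a natural extension but is not what "per observation" evaluation
means here.

`compare_models()` requires identical observation sets and ranks by
AUROC with elpd as tie-break. `run_pipeline()` chains all stages with
derived seeds and writes every artifact (panel, standardizer, draws,
odds-ratio tables, curve points, comparison) as CSV/JSON plus a manifest;
`render_report()` reproduces the headline surfaces (top-32 odds-ratio
table, per-submodel top-10 tables, comparison table) from the artifact
files without recomputation.

## Problem sizes used for validation

The test suite validates at sizes chosen for tight oracles rather than
realism: grid-integration posterior comparisons at 40–60 observations;
PSIS vs exact LOO at n = 40 with S = 4,000; interval coverage over 50
replicate cohorts of 1,000 participants (650 intervals); the
function-vs-medical headline on 10 replicate cohorts of 500 participants
with effects loaded only on function-change columns; moment calibration
at the full 2,944 and at 10,000 draws. The full-scale pipeline run
(2,944 participants, 4 chains x 1,000 draws, all four submodels) is the
package's intended use and takes tens of minutes on one core.

## Known limitations

* The generator's independence assumptions (across medical and functional
  variables, and MCAR wave missingness) are simplifications; both are the
  lightest structures consistent with the published statistics.
* Marginal per-column imputation does not borrow strength across
  covariates; cross-column imputation correlation is out of scope.
* The exact hierarchical structure and priors of the original analysis
  are not published in detail; ours are documented defaults, not claims
  about the original.
* The BNN's variational posterior underestimates uncertainty; width-scan
  conclusions rest on elpd differences whose SEs are reported for that
  reason.
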