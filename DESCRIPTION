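Package: fabwork
Title: Bayesian Prediction of Steady Work from Functional and Medical
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whether changes in self-reported function
    predict steady employment better than medical and health-care
    utilization measures, in cohorts patterned on the Supported
    Employment Demonstration. Provides a calibrated synthetic
    person-year panel generator, change-from-baseline design
    construction with standardization and missingness-tolerance
    filtering, Bayesian hierarchical logistic regression with latent
    imputation of missing covariates marginalized during inference,
    piecewise-linear Bayesian GLMs via additive coefficient
    decomposition, shallow Bayesian neural networks, and model
    comparison by Pareto-smoothed importance-sampling leave-one-out
    cross-validation with ROC and precision-recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
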