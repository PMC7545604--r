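Package: alspower
Title: Power Gains from Prognostic Model Covariates in Simulated ALS Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for evaluating whether machine-learning
    predictions of ALSFRS-R (the revised ALS functional rating scale), used as
    time-varying covariates in the primary analysis model, increase statistical
    power in randomized ALS clinical trials. Provides a synthetic longitudinal
    cohort generator with controlled baseline-covariate missingness, Little's
    MCAR test and an iterative random-forest imputer for mixed-type baseline
    tables, three ALSFRS-R predictors (random forest, random-intercept linear
    mixed model, and a cross-validated super learner), an external-validation
    toolkit (mean squared prediction error and observed-on-predicted regression
    diagnostics), a trial resampling engine with proportional shrinkage of
    change from baseline as the injected treatment effect, a mixed model for
    repeated measures (MMRM) with unstructured within-patient covariance for
    the treatment-by-visit analysis, and aggregation of replicate p-values into
    power curves, type-I-error estimates, win rates, and effective-sample-size
    gains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    lme4,
    glmnet,
    xgboost,
    pracma,
    nlme,
    jsonlite,
    yaml,
    withr,
    MASS
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
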