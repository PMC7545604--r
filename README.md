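# alspower

Simulation-based power analysis for ALS clinical trials whose primary
analysis adjusts for machine-learned predictions of each patient's ALSFRS-R
trajectory.

ALS trials measure disease progression with the 48-point ALSFRS-R functional
score. Because patients progress at very different rates, a large share of
outcome variance is prognostic rather than treatment-related, and a model
that predicts each patient's expected trajectory from baseline covariates can
be used as a covariate in the primary analysis to absorb that variance. This
package quantifies what that buys you: it simulates longitudinal trials by
resampling a synthetic trial-like patient pool, injects hypothetical
treatment effects, analyzes every simulated trial with seven competing
mixed-model-for-repeated-measures (MMRM) specifications, and reports type I
error, power, win rates, and the effective-sample-size gain of
prediction-adjusted analyses over conventional ones.

Everything runs on synthetic data from a built-in generator calibrated to
published summary characteristics of large ALS cohorts (baseline ALSFRS-R
around 38, average decline near one point per month), so no restricted
patient-level data are needed anywhere.

## What's in the box

| Module | Functions | Purpose |
|---|---|---|
| synth | `generator_params()`, `generate_cohort()`, `inject_baseline_missingness()`, `write_cohort()`/`read_cohort()` | synthetic longitudinal ALS cohorts with 22 baseline covariates, MCAR/MAR masking, lossless CSV round-trip |
| impute | `little_mcar_test()`, `missforest_impute()` | Little's MCAR diagnostic and a missForest-style iterative random-forest imputer |
| predict | `fit_rf()`, `fit_lme_predictor()`, `fit_superlearner()`, `predict_grid()` | three trajectory predictors over a shared covariate schema |
| validate | `prediction_metrics()`, `total_metrics()`, `change_metrics()`, `metrics_by_month()`, `holdout_split()` | MSPE and observed-on-predicted calibration diagnostics |
| trialsim | `trial_config()`, `sample_trial()`, `run_replicates()`, `apply_treatment_effect()` | resampling trial engine with effect injection `Y0 + (Y − Y0)(1 − E)` |
| mmrm | `analysis_specs()`, `build_design()`, `fit_mmrm()`, `treatment_pvalue()` | seven MMRM analysis models, unstructured covariance by REML, last-visit Wald test |
| evalpower | `estimate_power()`, `win_rates()`, `effective_sample_size()`, `power_summary()` | power with Monte-Carlo standard errors, win rates, ESS gains |
| iface | `read_run_config()`, `run_pipeline()`, `inst/cli/alspower.R` | YAML-config-driven end-to-end pipeline with a JSON run manifest |

See `vignette("alspower-methods")` (source under `vignettes/`) for the model
assumptions, parameter choices, generator realism limits, and numerical
details.

## Worked example

Generate a training cohort and a 509-patient, 12-month trial pool; mask
baseline covariates MAR and impute them back:

```r
library(alspower)

training <- generate_cohort(
  generator_params(n_patients = 1500, seed = 2024),
  schedule_days = round(c(0, 3, 6, 9, 12) * 30.44))
pool <- generate_cohort(generator_params(n_patients = 509, seed = 2025),
                        schedule_days = visit_schedule(12)$days)
training$baseline <- inject_baseline_missingness(training$baseline,
                                                 mechanism = "MAR", seed = 1)
little_mcar_test(training$baseline)
#> Little's MCAR test: d2 = 1259.125, df = 418, p = 3.767e-85 (47 patterns)

imp <- missforest_impute(training$baseline, seed = 2)
imp
#> missForest-style imputation: 5 sweep(s)
#> OOB error (NRMSE / PFC) per imputed column:
#>    site_of_onset onset_delta_days     riluzole_use             race
#>           0.2678           0.2569           0.3139           0.0720
#>      el_escorial   vital_capacity  diag_delta_days           weight
#>           0.4544           1.0077           0.3371           0.3637
#>              bmi           height
#>           0.4561           0.5987
training$baseline <- imp$completed
```

(The MAR masking is detectable by design — the test rejects MCAR decisively.)

Train a random-forest trajectory predictor and validate it externally on the
pool:

```r
ft <- build_feature_table(training)
rf <- fit_rf(ft$features, ft$outcome, rf_config(n_trees = 300, mtry = 8, seed = 3))

post_days <- visit_schedule(12)$days[-1]
grid <- predict_grid(rf, pool$baseline, post_days)
preds <- data.frame(patient_id = rep(pool$baseline$patient_id, times = 3),
                    day = rep(post_days, each = nrow(pool$baseline)),
                    pred = as.numeric(grid))
total_metrics(pool, preds)
#> MSPE = 18.812, R2 = 0.696, intercept = -3.200 (p = 1.45e-07), slope = 1.120 (n = 1527)
```

Simulate 500 trials with 200 patients and a 25% treatment effect, analyzed
with and without the prediction covariate:

```r
cfg <- trial_config(duration_months = 12, n_total = 200, effect_e = 0.25,
                    n_replicates = 500, master_seed = 4)
res <- run_replicates(pool, cfg,
                      specs = lapply(c("rf_pred", "no_extra"), analysis_spec),
                      models = list(rf = rf))
res
#> Simulated trials: 500 replicates, 12-month schedule, n = 200, E = 25%
#> Rejection rate at alpha = 0.05:
#>  rf_pred no_extra
#>    0.982    0.954

power_summary(list(res))
#>       spec n_total effect_e duration_months power       mc_se n_converged
#> 1  rf_pred     200     0.25              12 0.982 0.005945755         500
#> 2 no_extra     200     0.25              12 0.954 0.009368458         500
```

The full study — training cohort of 3160 patients, the complete n × E grid,
all seven analysis models, 2000 replicates per scenario — runs through the
config-driven pipeline:

```r
run_pipeline(read_run_config("my_config.yaml"))
# or from the shell:
# Rscript $(Rscript -e 'cat(system.file("cli", "alspower.R", package = "alspower"))') \
#     --config my_config.yaml --output-dir results/
```

Every pipeline run writes plain-text CSV/JSON artifacts plus a
`manifest.json` pinning the package version, R version, master seed, and full
configuration.

## Determinism

All randomness flows through explicit seeds; ranger/xgboost/glmnet run
single-threaded; replicate seeds derive deterministically from the master
seed so any single simulated trial can be reproduced in isolation; cohort
CSVs serialize doubles at 17 significant digits for bit-identical round
trips.
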