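---
title: "Methods: simulating ALS trials with machine-learned prognostic covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating ALS trials with machine-learned prognostic covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`alspower` studies a single design question: how much statistical power does a
longitudinal ALS trial gain when the primary analysis adjusts for a
model-based prediction of each patient's ALSFRS-R trajectory, compared with
conventional covariate choices? Because individual-level ALS registry and
trial data are access-restricted, the package answers the question entirely
on synthetic data: it ships a generator calibrated to published summary
characteristics of large ALS cohorts, and every downstream number is computed
from cohorts produced by that generator under a fixed seed.

## The synthetic cohort generator

Each patient $i$ has a latent linear ALSFRS-R trajectory

$$Y_{ij} = \mathrm{round}\big(\mathrm{clamp}(b_{0i} + s_i\, t_{ij} + \varepsilon_{ij},\ 0,\ 48)\big),$$

with $t_{ij}$ the visit time in months, $b_{0i}$ a truncated-normal latent
baseline (mean 38, SD 5, truncated to $[10, 48]$), $s_i$ a normal latent
slope (mean $-0.9$ points/month, SD 0.45) shifted by onset site and vital
capacity, and $\varepsilon_{ij}$ i.i.d. normal residuals (SD 3) with
$\varepsilon_{i0}=0$ so the recorded baseline equals the day-0 visit. Months
are converted to days at 30.44 days/month. The defaults were chosen to
reproduce, at cohort scale, the baseline mean near 38 and the roughly one
point per month average decline reported for large ALS trial populations;
they are package choices, not estimates from any restricted dataset.

Key modelling decisions:

* **Linearity.** Mean decline is linear in time. Real ALSFRS-R trajectories
  show floor effects and occasional plateaus; the clamp at $[0, 48]$ and the
  rounding reproduce the floor but not plateaus. This is the generator's main
  realism limit, and it is deliberate: a linear truth makes the mixed-model
  predictor correctly specified, which gives the power comparison a clean
  best case to measure the machine-learning predictors against.
* **Pre-baseline slope.** The covariate `preslope_total` is
  $-(48 - Y_{i0}) / d_i$ (points per month), where $d_i$ is days from symptom
  onset to baseline. The generator constructs $d_i$ from a noisy copy of the
  latent decline rate so that the preslope correlates with the true slope at
  a configurable level (`preslope_slope_corr`, default 0.6). This single
  number controls how informative the best baseline covariate can be, and
  therefore how much room the trajectory predictors have to improve on it.
* **Covariate schema.** 22 baseline features are generated: 11 demographic
  and history variables (age, sex, onset site, El Escorial category, riluzole
  use, onset and diagnosis delays, BMI, height, weight, race), the baseline
  total score with its four subscores (bulbar, fine motor, gross motor,
  respiratory; allocated multinomially with a cap of 12 per domain) and vital
  capacity, four preslopes, and days on study. Only onset site and vital
  capacity actually shift the latent slope; the rest are realistic
  distractors that a flexible learner must learn to ignore.
* **Missingness.** Baseline covariates can be masked MCAR or MAR. The MAR
  mechanism makes missingness a logistic function of observed age and
  baseline score (older, faster-progressing patients have more gaps), with
  the intercept solved numerically so each column hits its target rate.
  Default rates concentrate in BMI and height (42%), mimicking the pattern
  of pooled legacy trial databases where anthropometry is often absent.

## Imputation and its diagnostic

Training cohorts are completed with a from-scratch implementation of the
missForest algorithm (mean/mode initialization, columns visited in order of
increasing missingness, one random forest per column and sweep, per-type
stopping at the first increase of the change statistic, the pre-increase
snapshot returned). The implementation is hand-rolled because the algorithm's
stopping rule and returned iteration are part of what the package tests; 100
trees per column and at most 10 sweeps are the package defaults.

Before imputing, `little_mcar_test()` computes Little's MCAR statistic
$d^2 = \sum_p n_p(\bar y_p - \hat\mu_p)^\top \hat\Sigma_{oo,p}^{-1}(\bar y_p - \hat\mu_p)$
with $\hat\mu, \hat\Sigma$ from a hand-rolled EM for the multivariate normal
(tolerance $10^{-6}$, ridge $10^{-8}$ on observed sub-blocks). Singleton
missingness patterns are merged into the nearest (Hamming distance) pattern
whose observed set is a subset of theirs, otherwise dropped and counted. The
chi-square approximation is asymptotic per pattern; in our calibration the
test holds its 5% size from roughly 150 rows per pattern upward, so the
package's own size checks use $n \ge 300$ with two masked columns.

## The three trajectory predictors

All predictors map (baseline covariates, day on study) to an expected
ALSFRS-R total score, and are fitted on a training cohort disjoint from the
trial pool:

* **Random forest** (`fit_rf`): 500 trees, `mtry = 8`, single-threaded for
  reproducibility. The out-of-bag error stored on the fit is recomputable
  from the per-tree predictions and inbag counts, and the test suite verifies
  the recomputation to $10^{-10}$.
* **Linear mixed-effects model** (`fit_lme_predictor`): REML fit of
  `y ~ y0 + preslope + day + age + onset_delta + (1 | patient)`. Predictions
  for new patients use fixed effects only. Under the generator this model is
  close to correctly specified.
* **Super learner** (`fit_superlearner`): stacking of four base learners
  (gradient-boosted trees, ordinary least squares, random forest, elastic
  net) on 10-fold cross-validation, grouped by patient so no patient
  straddles folds. The stacking weights are the exact minimizer of the
  out-of-fold squared error over the probability simplex, computed by
  active-set enumeration over learner subsets (the number of learners is
  small, so exact enumeration is cheap and removes any grid-resolution
  artifact).

External validity is summarized by `prediction_metrics()`: mean squared
prediction error plus the regression of observed on predicted (R², intercept
with its t-test as a bias measure, slope as a calibration measure), on the
total-score scale, the change-from-baseline scale, and stratified by month.

## Trial simulation

Simulated trials resample patients **without replacement** from a synthetic
509-patient, 12-month trial-like pool (visits at months 0, 1, 6, 12),
randomize 1:1, and inject a hypothetical treatment effect of size $E$ by
shrinking the active arm's change from baseline:

$$Y^{trt}_{ij} = Y_{i0} + (Y_{ij} - Y_{i0})(1 - E).$$

$E = 0$ leaves the data bit-identical, which is what makes the type I error
runs a pure test of the analysis model. Replicate seeds are derived
deterministically from a master seed, so any single replicate can be
reproduced in isolation.

## Analysis models

The primary analysis is a mixed model for repeated measures (MMRM) on change
from baseline: intercept, baseline score, model-specific extra covariates,
visit indicators, and one treatment-by-visit interaction per post-baseline
visit, with an **unstructured** within-patient covariance estimated by REML.
The treatment is tested through the interaction at the last scheduled visit
(two-sided Wald z).

Seven specifications are compared: three use a trajectory prediction as a
time-varying covariate (`rf_pred`, `lme_pred`, `sl_pred` — the covariate's
value changes by visit), `single_best_predictor` adjusts for the total-score
preslope, `standard_baseline` for onset-site and El Escorial indicators,
`no_extra` for nothing beyond the baseline score, and `full` combines the RF
prediction, preslope, and the standard indicators. Predictions are computed
once per pool from baseline covariates and visit day — never from the arm or
from effect-adjusted outcomes — so adjusting for them cannot bias the null.

Numerically, complete-visit replicates are fitted by a dedicated EM-REML
solver whose per-iteration cost is $O(J^2 p^2)$ after precomputing per-visit
cross-products (about 6 ms per fit at $n = 200$, $J = 3$); it matches
`nlme::gls` to about $10^{-5}$ on shared problems and the saturated
group-means oracle to machine precision. Replicates with missing visits fall
back to `nlme::gls` with `corSymm`/`varIdent` (exact likelihood, slower), and
non-converged unstructured fits are refitted with compound symmetry and
flagged. Convergence tolerance is $10^{-10}$ on the relative change of the
covariance.

## Power, win rates, effective sample size

`estimate_power()` reports the rejection rate at $\alpha = 0.05$ with its
binomial Monte-Carlo standard error; non-converged replicates are excluded
from the denominator and counted. `win_rates()` reports how often each
analysis model yields the smallest p-value (ties split). Effective sample
size compares isotonically smoothed, linearly interpolated power curves on a
shared enrollment grid: the gain is the extra enrollment the reference
analysis would need to match the adjusted analysis's power, with no
extrapolation beyond the simulated grid (out-of-range targets are flagged
rather than guessed).

## Problem sizes and runtime

The package's default study (see `read_run_config()`) uses a training cohort
of 3160 patients with quarterly visits over a year, a 509-patient pool,
enrollment grid {120, 200, 280, 360}, effects {0, 25%, 40%}, and 2000
replicates per scenario. On one CPU: cohort generation takes about a second,
imputation about 30 s, the three predictors about 100 s, and 2000 replicates
of all seven analysis models about a minute. These sizes were chosen so a
full type-I-error and power evaluation completes in minutes while keeping the
Monte-Carlo standard error at the null near 0.005.

## Reproducibility

All randomness flows through explicit seeds (`withr::with_seed`); ranger,
xgboost, and glmnet run single-threaded; cohort CSVs serialize doubles with
17 significant digits so a written-and-reread cohort is bit-identical.
`run_pipeline()` writes a JSON manifest (package version, R version, master
seed, full config) next to its outputs.
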