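test_that("visit schedules follow the published designs in rounded days", {
  s6 <- visit_schedule(6)
  expect_identical(s6$visit_months, c(0, 1, 2, 3, 6))
  expect_identical(s6$days, round(c(0, 1, 2, 3, 6) * 30.44))
  expect_identical(visit_schedule(12)$visit_months, c(0, 1, 6, 12))
  expect_identical(visit_schedule(18)$visit_months, c(0, 1, 6, 12, 18))
  expect_error(visit_schedule(9), "6, 12, or 18")
})

test_that("the effect transform is exact arithmetic with identity at zero", {
  expect_identical(apply_treatment_effect(40, 30, 0), 30)
  # E = 0.4 keeps 60% of a 10-point decline: 40 - 6 = 34
  expect_equal(apply_treatment_effect(40, 30, 0.4), 34)
  # no change from baseline is preserved under any effect
  expect_equal(apply_treatment_effect(35, 35, 0.7), 35)
  expect_error(apply_treatment_effect(40, 30, 1), "\\[0, 1\\)")
  expect_error(apply_treatment_effect(40, 30, -0.1), "\\[0, 1\\)")
})

test_that("a sampled trial draws distinct patients split 1:1", {
  pool <- fixture_pool()
  cfg <- trial_config(duration_months = 12, n_total = 120, effect_e = 0,
                      master_seed = 7)
  tr <- sample_trial(pool, cfg, replicate_seed = 99)
  expect_identical(nrow(tr$patients), 120L)
  expect_identical(anyDuplicated(tr$patients$patient_id), 0L)
  expect_identical(as.vector(table(tr$patients$arm)), c(60L, 60L))
  expect_identical(dim(tr$y_observed), c(120L, 3L))
  # baseline rows stay aligned with the sampled patients
  expect_identical(tr$baseline$patient_id, tr$patients$patient_id)
})

test_that("zero effect leaves sampled outcomes bit-identical to the pool", {
  pool <- fixture_pool()
  cfg <- trial_config(n_total = 100, effect_e = 0, master_seed = 3)
  tr <- sample_trial(pool, cfg, replicate_seed = 5)
  arr <- alspower:::pool_arrays(pool, cfg$schedule)
  expect_identical(unname(tr$y_observed), unname(arr$ypost[tr$pool_index, ]))
  expect_identical(tr$y0, unname(arr$y0[tr$pool_index]))
})

test_that("the effect shrinks only active-arm change from baseline", {
  pool <- fixture_pool()
  cfg0 <- trial_config(n_total = 100, effect_e = 0, master_seed = 3)
  cfg4 <- trial_config(n_total = 100, effect_e = 0.4, master_seed = 3)
  t0 <- sample_trial(pool, cfg0, replicate_seed = 5)
  t4 <- sample_trial(pool, cfg4, replicate_seed = 5)
  expect_identical(t0$pool_index, t4$pool_index)
  plac <- t0$patients$arm == "placebo"
  expect_identical(t4$y_observed[plac, ], t0$y_observed[plac, ])
  act <- !plac
  expect_equal(t4$y_change[act, ], t0$y_change[act, ] * 0.6, tolerance = 1e-12)
})

test_that("replicates are deterministic in the master seed and differ across indexes", {
  pool <- fixture_pool()
  cfg <- trial_config(n_total = 60, effect_e = 0, n_replicates = 4,
                      master_seed = 42)
  a <- run_replicates(pool, cfg, specs = analysis_spec("no_extra"))
  b <- run_replicates(pool, cfg, specs = analysis_spec("no_extra"))
  expect_identical(a$p_values, b$p_values)
  t1 <- sample_trial(pool, cfg, replicate_seed = alspower:::child_seed(42, 1))
  t2 <- sample_trial(pool, cfg, replicate_seed = alspower:::child_seed(42, 2))
  expect_false(identical(t1$pool_index, t2$pool_index))
})

test_that("sampling is without replacement and refuses oversized draws", {
  pool <- fixture_pool()
  expect_error(sample_trial(pool, trial_config(n_total = 600)),
               "without replacement")
  cfg <- trial_config(n_total = 508)
  tr <- sample_trial(pool, cfg, replicate_seed = 1)
  expect_identical(anyDuplicated(tr$pool_index), 0L)
  expect_error(trial_config(n_total = 121), "even")
})

test_that("prediction specs require a fitted model and use pool-level grids", {
  pool <- fixture_pool()
  cfg <- trial_config(n_total = 80, n_replicates = 2, master_seed = 8)
  expect_error(run_replicates(pool, cfg, specs = analysis_spec("rf_pred")),
               "models")
  models <- fixture_models()
  res <- run_replicates(pool, cfg, specs = analysis_spec("rf_pred"),
                        models = list(rf = models$rf))
  expect_identical(dim(res$p_values), c(2L, 1L))
  expect_true(all(res$p_values > 0 & res$p_values < 1))
})

test_that("precomputed prediction matrices give the same p-values as models", {
  pool <- fixture_pool()
  models <- fixture_models()
  cfg <- trial_config(n_total = 80, n_replicates = 3, master_seed = 12)
  post <- cfg$schedule$days[cfg$schedule$days > 0]
  grids <- list(rf = predict_grid(models$rf, pool$baseline, post))
  via_models <- run_replicates(pool, cfg, specs = analysis_spec("rf_pred"),
                               models = list(rf = models$rf))
  via_grids <- run_replicates(pool, cfg, specs = analysis_spec("rf_pred"),
                              predictions = grids)
  expect_identical(via_models$p_values, via_grids$p_values)
})

test_that("under no effect the p-value distribution is roughly uniform", {
  pool <- fixture_pool()
  cfg <- trial_config(n_total = 200, effect_e = 0, n_replicates = 200,
                      master_seed = 314)
  res <- run_replicates(pool, cfg, specs = analysis_spec("no_extra"))
  p <- res$p_values[, 1L]
  expect_true(all(is.finite(p)))
  # rejection at three alpha levels within 3 binomial MC SEs
  for (a in c(0.1, 0.25, 0.5)) {
    expect_lt(abs(mean(p < a) - a), 3 * sqrt(a * (1 - a) / 200) + 1e-9)
  }
})
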