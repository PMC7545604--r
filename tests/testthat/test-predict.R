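test_that("the pre-baseline slope follows its defining ratio", {
  # 48 -> 36 over 300 days: 12 points lost, expressed per day
  expect_equal(compute_preslope(36, 48, 300), 12 / 300)
  # a baseline at the ceiling implies no measurable pre-study decline
  expect_identical(compute_preslope(48, 48, 300), 0)
  expect_error(compute_preslope(40, 48, 0), "> 0")
  expect_error(compute_preslope(50, 48, 300), "max_score")
})

test_that("the feature table matches the declared covariate schema", {
  ds <- fixture_pool()
  ft <- build_feature_table(ds)
  expect_setequal(names(ft$features),
                  unlist(covariate_schema(), use.names = FALSE))
  expect_identical(nrow(ft$features), length(ft$outcome))
  expect_false(anyNA(ft$outcome))
  # one row per post-baseline observation per patient
  expect_identical(nrow(ft$features),
                   sum(ds$visits$day > 0 & !is.na(ds$visits$alsfrs_r)))
})

test_that("the stored OOB error equals a from-scratch recomputation over trees", {
  models <- fixture_models()
  rf <- models$rf
  expect_lt(abs(rf$oob_mse - rf_oob_error(rf)), 1e-10)
})

test_that("random forest predictions are deterministic and improve on the mean", {
  ds <- fixture_pool()
  models <- fixture_models()
  split <- holdout_split(fixture_training(), test_fraction = 0.25, seed = 5)
  ft <- build_feature_table(split$test)
  p1 <- predict(models$rf, ft$features, days = ft$features$days_on_study)
  p2 <- predict(models$rf, ft$features, days = ft$features$days_on_study)
  expect_identical(p1, p2)
  mse_rf <- mean((ft$outcome - p1)^2)
  mse_mean <- mean((ft$outcome - mean(ft$outcome))^2)
  expect_lt(mse_rf, 0.5 * mse_mean)
})

test_that("mtry tuning returns the out-of-bag argmin on the searched grid", {
  ds <- fixture_pool()
  ft <- build_feature_table(ds)
  grid <- c(3L, 8L, 14L)
  tuned <- tune_rf_mtry(ft$features, ft$outcome,
                        config = rf_config(n_trees = 60, seed = 15),
                        candidates = grid)
  expect_true(tuned$mtry %in% grid)
  expect_identical(tuned$mtry, grid[which.min(tuned$oob_errors)])
})

test_that("the mixed-model predictor recovers the generating coefficients", {
  train <- fixture_training()
  fit <- fit_lme_predictor(train)
  # outcome is linear in time with latent slope mean -0.9 points/month
  day_hat <- fit$beta[["day"]]
  day_se <- fit$beta_se[["day"]]
  expect_lt(abs(day_hat - (-0.9 / 30.44)), 3 * day_se)
  expect_gt(fit$sigma_b2, 0)
})

test_that("mixed-model predictions use fixed effects only, so new patients score identically", {
  models <- fixture_models()
  ds <- fixture_pool()
  p <- predict(models$lme, ds$baseline, days = 183)
  # duplicated covariate rows must get identical predictions
  p2 <- predict(models$lme, ds$baseline[c(1L, 1L), , drop = FALSE], days = 183)
  expect_identical(p2[1L], p2[2L])
  expect_identical(length(p), nrow(ds$baseline))
})

test_that("exact simplex weights solve small problems with a known answer", {
  # one perfect learner: all weight goes to it
  withr::with_seed(7, {
    y <- rnorm(200)
    Z <- cbind(y, y + rnorm(200, sd = 2), rnorm(200))
  })
  w <- alspower:::simplex_weights(Z, y)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gt(w[1L], 0.99)
  # the exact solution is at least as good as every 0.01 grid point
  grid <- seq(0, 1, by = 0.01)
  best_grid <- Inf
  for (a in grid) for (b in grid[grid <= 1 - a + 1e-12]) {
    wc <- c(a, b, 1 - a - b)
    if (wc[3L] < -1e-12) next
    best_grid <- min(best_grid, mean((y - Z %*% pmax(wc, 0))^2))
  }
  expect_lte(mean((y - Z %*% w)^2), best_grid + 1e-6)
})

test_that("super-learner weights lie on the simplex and the ensemble beats its parts out of fold", {
  models <- fixture_models()
  sl <- models$sl
  expect_true(all(sl$weights >= -1e-12))
  expect_equal(sum(sl$weights), 1, tolerance = 1e-10)
  expect_lte(sl$oof_risk, min(sl$cv_risk) + 1e-8)
})

test_that("super-learner folds respect patient grouping", {
  models <- fixture_models()
  folds <- models$sl$folds
  ft <- build_feature_table(fixture_training())
  # all rows of a patient share one fold
  per_patient <- tapply(folds, ft$patient_id, function(f) length(unique(f)))
  expect_true(all(per_patient == 1L))
})

test_that("prediction grids have one column per requested day and respect determinism", {
  ds <- fixture_pool()
  models <- fixture_models()
  days <- visit_schedule(12)$days
  post <- days[days > 0]
  g <- predict_grid(models$rf, ds$baseline, post)
  expect_identical(dim(g), c(nrow(ds$baseline), length(post)))
  expect_identical(g, predict_grid(models$rf, ds$baseline, post))
  # later predicted scores should be lower on average (disease progresses)
  expect_lt(mean(g[, ncol(g)]), mean(g[, 1L]))
})
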