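# Shared small trial replicate for the MMRM tests.
mmrm_fixture <- function(effect = 0, n = 120, seed = 17) {
  memo(sprintf("mmrm_trial_%g_%d_%d", effect, n, seed), {
    pool <- fixture_pool()
    cfg <- trial_config(duration_months = 12, n_total = n, effect_e = effect,
                        master_seed = seed)
    sample_trial(pool, cfg, replicate_seed = seed)
  })
}

test_that("all seven analysis specifications are available with the expected covariates", {
  specs <- analysis_specs()
  expect_named(specs, c("rf_pred", "lme_pred", "sl_pred",
                        "single_best_predictor", "standard_baseline",
                        "no_extra", "full"))
  expect_identical(specs$single_best_predictor$extras$baseline, "preslope_total")
  expect_setequal(specs$standard_baseline$extras$baseline,
                  c("site_bulbar", "el_definite"))
  expect_identical(specs$no_extra$extras, list())
  expect_identical(specs$full$extras$prediction, "rf")
  expect_error(analysis_spec("bogus"))
})

test_that("the design matrix has the documented layout", {
  tr <- mmrm_fixture()
  des <- build_design(tr, analysis_spec("standard_baseline"))
  J <- length(tr$post_days)
  expect_identical(des$columns,
                   c("intercept", "y0", "site_bulbar", "el_definite",
                     paste0("visit", 2:J), paste0("trt_visit", 1:J)))
  # outcome is change from baseline
  expect_equal(des$y, tr$y_observed - tr$y0, ignore_attr = TRUE)
  # the treatment interaction at visit j is nonzero only at visit j, active arm
  x2 <- des$x[[2L]]
  expect_true(all(x2[, "trt_visit1"] == 0))
  expect_identical(unname(x2[, "trt_visit2"]),
                   as.numeric(tr$patients$arm == "active"))
})

test_that("time-varying prediction covariates differ across visit design blocks", {
  tr <- mmrm_fixture()
  models <- fixture_models()
  grid <- predict_grid(models$rf, tr$baseline, tr$post_days)
  des <- build_design(tr, analysis_spec("rf_pred"), predictions = list(rf = grid))
  expect_identical(unname(des$x[[1L]][, "pred"]), unname(grid[, 1L]))
  expect_identical(unname(des$x[[3L]][, "pred"]), unname(grid[, 3L]))
  expect_false(identical(des$x[[1L]][, "pred"], des$x[[3L]][, "pred"]))
})

test_that("the saturated MMRM reproduces per-arm per-visit mean changes exactly", {
  tr <- mmrm_fixture()
  ok <- stats::complete.cases(tr$y_change)
  tr2 <- tr
  tr2$y_observed <- tr$y_observed[ok, , drop = FALSE]
  tr2$y_change <- tr$y_change[ok, , drop = FALSE]
  tr2$y0 <- tr$y0[ok]
  tr2$patients <- tr$patients[ok, , drop = FALSE]
  tr2$baseline <- tr$baseline[ok, , drop = FALSE]
  des <- build_design(tr2, analysis_spec("no_extra"), include_baseline = FALSE)
  fit <- fit_mmrm(des)
  expect_true(fit$converged)
  act <- tr2$patients$arm == "active"
  J <- ncol(tr2$y_change)
  for (j in seq_len(J)) {
    diff_j <- mean(tr2$y_change[act, j]) - mean(tr2$y_change[!act, j])
    expect_lt(abs(fit$gamma[[paste0("trt_visit", j)]] - diff_j), 1e-6)
  }
})

test_that("Wald p-values equal the closed-form normal tail formula", {
  tr <- mmrm_fixture()
  des <- build_design(tr, analysis_spec("no_extra"))
  fit <- fit_mmrm(des)
  expect_true(fit$converged)
  manual <- 2 * pnorm(-abs(fit$gamma / fit$gamma_se))
  expect_lt(max(abs(fit$p_values - manual)), 1e-12)
  expect_identical(treatment_pvalue(fit),
                   unname(fit$p_values[length(fit$p_values)]))
})

test_that("the fast REML solver agrees with the reference generalized-least-squares fit", {
  tr <- mmrm_fixture(n = 100, seed = 23)
  ok <- stats::complete.cases(tr$y_change)
  tr2 <- tr
  for (nm in c("y_observed", "y_change")) tr2[[nm]] <- tr[[nm]][ok, , drop = FALSE]
  tr2$y0 <- tr$y0[ok]; tr2$patients <- tr$patients[ok, , drop = FALSE]
  tr2$baseline <- tr$baseline[ok, , drop = FALSE]
  des <- build_design(tr2, analysis_spec("no_extra"))
  fast <- fit_mmrm(des)
  ref <- alspower:::mmrm_gls(des$y, des$x, des$columns)
  expect_lt(max(abs(fast$beta - ref$beta)), 1e-3)
  expect_lt(max(abs(sqrt(diag(fast$vcov_beta)) - sqrt(diag(ref$vcov)))), 1e-3)
  expect_lt(max(abs(fast$covariance - ref$sigma)) / max(abs(ref$sigma)), 1e-3)
})

test_that("incomplete visit data are analyzed by likelihood, not deletion", {
  tr <- mmrm_fixture(n = 150, seed = 29)
  if (!anyNA(tr$y_change)) {
    tr$y_change[1:5, 2L] <- NA
    tr$y_observed[1:5, 2L] <- NA
  }
  des <- build_design(tr, analysis_spec("no_extra"))
  fit <- fit_mmrm(des)
  expect_true(fit$converged)
  expect_identical(length(fit$gamma), ncol(tr$y_change))
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
})

test_that("the estimated covariance is symmetric positive definite", {
  tr <- mmrm_fixture()
  des <- build_design(tr, analysis_spec("no_extra"))
  fit <- fit_mmrm(des)
  s <- fit$covariance
  expect_equal(s, t(s), tolerance = 1e-8)
  expect_true(all(eigen(s, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("compound symmetry is a genuine restriction of the unstructured fit", {
  tr <- mmrm_fixture()
  des <- build_design(tr, analysis_spec("no_extra"))
  fit <- fit_mmrm(des, covariance = "compound_symmetry")
  s <- fit$covariance
  expect_lt(max(abs(diag(s) - mean(diag(s)))), 1e-6)
  off <- s[upper.tri(s)]
  expect_lt(max(abs(off - mean(off))), 1e-6)
})

test_that("non-converged fits surface an NA p-value with a reason", {
  fit <- structure(list(converged = FALSE), class = "mmrm_fit")
  pv <- treatment_pvalue(fit)
  expect_true(is.na(pv))
  expect_match(attr(pv, "reason"), "converged")
})

test_that("a one-armed design is rejected", {
  tr <- mmrm_fixture()
  tr$patients$arm <- "active"
  des <- build_design(tr, analysis_spec("no_extra"))
  expect_error(fit_mmrm(des), "both arms")
})
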