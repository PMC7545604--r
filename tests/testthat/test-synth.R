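test_that("an empty cohort yields valid empty tables", {
  ds <- generate_cohort(generator_params(n_patients = 0), c(0, 365))
  expect_s3_class(ds, "longitudinal_dataset")
  expect_identical(nrow(ds$baseline), 0L)
  expect_identical(nrow(ds$visits), 0L)
  expect_named(ds$visits, c("patient_id", "day", "alsfrs_r"))
})

test_that("noise-free trajectories follow the linear decline arithmetic", {
  p <- generator_params(n_patients = 4, baseline_mean = 38, baseline_sd = 0,
                        slope_mean = -0.9, slope_sd = 0, residual_sd = 0,
                        covariate_effects = c(), seed = 3)
  ds <- generate_cohort(p, c(0, 365))
  expect_true(all(ds$visits$alsfrs_r[ds$visits$day == 0] == 38))
  expected <- round(min(max(38 - 0.9 * 365 / 30.44, 0), 48))
  expect_true(all(ds$visits$alsfrs_r[ds$visits$day == 365] == expected))
})

test_that("default-parameter cohorts land in the published baseline band", {
  ds <- generate_cohort(generator_params(n_patients = 3160, seed = 7),
                        c(0, 91, 183, 274, 365))
  m <- mean(ds$baseline$baseline_frs)
  expect_gt(m, 37.0)
  expect_lt(m, 39.0)
})

test_that("exported scores are integers in range with an exact day-0 row", {
  ds <- fixture_pool()
  expect_true(all(ds$visits$alsfrs_r >= 0 & ds$visits$alsfrs_r <= 48))
  expect_type(ds$visits$alsfrs_r, "integer")
  d0 <- ds$visits[ds$visits$day == 0, ]
  expect_identical(d0$patient_id, ds$baseline$patient_id)
  expect_identical(as.integer(d0$alsfrs_r), ds$baseline$baseline_frs)
  subs <- ds$baseline[, c("sub_bulbar", "sub_fine_motor", "sub_gross_motor",
                          "sub_respiratory")]
  expect_true(all(as.matrix(subs) >= 0 & as.matrix(subs) <= 12))
  expect_identical(as.integer(rowSums(subs)), ds$baseline$baseline_frs)
  expect_true(all(ds$baseline$onset_delta_days > 0))
})

test_that("same parameters and seed give bit-identical cohorts, also via CSV", {
  p <- generator_params(n_patients = 150, seed = 11)
  a <- generate_cohort(p, c(0, 30, 183, 365))
  b <- generate_cohort(p, c(0, 30, 183, 365))
  expect_identical(a, b)
  da <- withr::local_tempdir()
  db <- withr::local_tempdir()
  write_cohort(a, da)
  write_cohort(b, db)
  expect_identical(readLines(file.path(da, "baseline.csv")),
                   readLines(file.path(db, "baseline.csv")))
  rt <- read_cohort(da)
  expect_identical(rt$visits$alsfrs_r, a$visits$alsfrs_r)
  for (nm in names(a$baseline)) {
    expect_identical(rt$baseline[[nm]], a$baseline[[nm]], label = nm)
  }
})

test_that("the exported preslope tracks the hidden latent rate at the requested correlation", {
  for (rho in c(0.3, 0.6, 0.9)) {
    p <- generator_params(n_patients = 1500, preslope_slope_corr = rho, seed = 5)
    ds <- generate_cohort(p, c(0, 183, 365))
    pre <- (48 - ds$baseline$baseline_frs) / ds$baseline$onset_delta_days
    expect_lt(abs(abs(cor(pre, ds$latent$latent_rate)) - rho), 0.1)
  }
})

test_that("disjoint-seed cohorts are exchangeable in baseline score", {
  pvals <- vapply(1:8, function(i) {
    a <- generate_cohort(generator_params(n_patients = 400, seed = 1000 + i),
                         c(0, 183))
    b <- generate_cohort(generator_params(n_patients = 400, seed = 2000 + i),
                         c(0, 183))
    suppressWarnings(ks.test(a$baseline$baseline_frs,
                             b$baseline$baseline_frs)$p.value)
  }, numeric(1L))
  # discrete ties make the KS test conservative; rejections stay at or below
  # the nominal rate
  expect_lte(sum(pvals < 0.05), 2)
})

test_that("rate-zero masking is the identity and MCAR hits the target rate", {
  ds <- fixture_pool()
  same <- inject_baseline_missingness(ds$baseline, rates = c(bmi = 0), seed = 1)
  expect_identical(same, ds$baseline)
  big <- generate_cohort(generator_params(n_patients = 3160, seed = 77), c(0, 183))
  masked <- inject_baseline_missingness(big$baseline, rates = c(bmi = 0.4),
                                        mechanism = "MCAR", seed = 2)
  frac <- mean(is.na(masked$bmi))
  se <- sqrt(0.4 * 0.6 / 3160)
  expect_lt(abs(frac - 0.4), 3 * se)
})

test_that("default missingness concentrates in BMI and height", {
  rates <- default_missing_rates()
  expect_gt(rates[["bmi"]], 0.4)
  expect_gt(rates[["height"]], 0.4)
  expect_true(all(rates[setdiff(names(rates), c("bmi", "height"))] <= 0.25))
})

test_that("MAR masking depends on observed age", {
  big <- generate_cohort(generator_params(n_patients = 3000, seed = 88), c(0, 183))
  masked <- inject_baseline_missingness(big$baseline,
                                        rates = c(vital_capacity = 0.3),
                                        mechanism = "MAR", seed = 3)
  g <- glm(is.na(masked$vital_capacity) ~ big$baseline$age, family = binomial)
  expect_gt(coef(g)[2L], 0)
  expect_lt(summary(g)$coefficients[2L, 4L], 0.01)
})

test_that("generator rejects invalid inputs", {
  expect_error(generator_params(n_patients = -1), "n_patients")
  expect_error(generator_params(baseline_sd = -1), "baseline_sd")
  expect_error(generator_params(missing_rates = c(bmi = 1.2)), "0, 1")
  expect_error(generate_cohort(generator_params(1), c(30, 0)), "increasing")
  expect_error(generate_cohort(generator_params(1), c(30, 60)), "start at 0")
})

test_that("optional dropout removes later visits monotonically", {
  p <- generator_params(n_patients = 300, dropout_hazard = 0.1, seed = 9)
  ds <- generate_cohort(p, c(0, 30, 183, 365))
  expect_lt(nrow(ds$visits), 300 * 4)
  # monotone: a patient observed at a later day is observed at all earlier days
  tab <- table(ds$visits$patient_id)
  for (pid in names(tab)[tab < 4]) {
    d <- sort(ds$visits$day[ds$visits$patient_id == pid])
    expect_identical(d, c(0, 30, 183, 365)[seq_along(d)])
  }
})
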