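# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Trial-like patient pool on the 12-month schedule (defaults, fixed seed).
fixture_pool <- function() {
  memo("pool", generate_cohort(generator_params(n_patients = 509, seed = 101),
                               visit_schedule(12)$days))
}

# Training cohort used by the heavier tests; smaller than the full study
# cohort to keep the suite fast, quarterly visits over a year.
fixture_training <- function(n = 1200) {
  memo(paste0("train", n), {
    days <- unique(round(c(0, 3, 6, 9, 12) * 30.44))
    generate_cohort(generator_params(n_patients = n, seed = 202), days)
  })
}

fixture_models <- function() {
  memo("models", {
    train <- fixture_training()
    ft <- build_feature_table(train)
    rf <- fit_rf(ft$features, ft$outcome, rf_config(n_trees = 200, mtry = 8, seed = 33))
    lme <- fit_lme_predictor(train)
    sl <- suppressWarnings(
      fit_superlearner(ft$features, ft$outcome, k_folds = 10, seed = 44,
                       learners = default_learners(rf_trees = 100, xgb_rounds = 80),
                       group = ft$patient_id))
    list(rf = rf, lme = lme, sl = sl)
  })
}

# Long prediction table (patient_id, day, pred) for a dataset's post-baseline
# schedule, as consumed by the validation metrics.
pool_pred_table <- function(model, ds) {
  post <- ds$schedule_days[ds$schedule_days > 0]
  pm <- predict_grid(model, ds$baseline, post)
  data.frame(patient_id = rep(ds$baseline$patient_id, times = length(post)),
             day = rep(post, each = nrow(ds$baseline)),
             pred = as.numeric(pm))
}

# A small correlated multivariate-normal data.frame with optional MCAR mask.
mvn_frame <- function(n, k, rho = 0.5, mask_rate = 0, mask_cols = seq_len(k),
                      seed = 1) {
  withr::with_seed(seed, {
    S <- matrix(rho, k, k); diag(S) <- 1
    x <- matrix(stats::rnorm(n * k), n, k) %*% chol(S)
    df <- as.data.frame(x)
    names(df) <- paste0("v", seq_len(k))
    truth <- df
    if (mask_rate > 0) {
      for (j in mask_cols) {
        df[[j]][stats::runif(n) < mask_rate] <- NA
      }
    }
    list(df = df, truth = truth)
  })
}
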