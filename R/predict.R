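#' ALSFRS-R predictors and the covariate derivations they consume
#'
#' Three candidate predictors of the ALSFRS-R total score at a post-baseline
#' day are provided: a random forest, a random-intercept linear mixed model,
#' and a cross-validated super learner stacking four base learners. All three
#' consume the same candidate-covariate schema: days on study, baseline
#' demographics, baseline functional scores, and pre-study progression rates
#' ("preslopes") derived from baseline scores and the time from symptom onset
#' to baseline.
#'
#' @name predict-models
NULL

#' Candidate covariate schema
#'
#' Names the covariates offered to the predictors: 11 baseline demographics,
#' 6 baseline functional scores (total ALSFRS-R, four domain subscores, vital
#' capacity), 4 derived preslopes, and the time variable `days_on_study`.
#'
#' @return a list of class `covariate_schema`.
#' @export
covariate_schema <- function() {
  sch <- list(
    demographic_names = c("age", "sex", "site_of_onset", "el_escorial",
                          "riluzole_use", "onset_delta_days", "diag_delta_days",
                          "bmi", "height", "weight", "race"),
    score_names = c("baseline_frs", "sub_bulbar", "sub_fine_motor",
                    "sub_gross_motor", "sub_respiratory", "vital_capacity"),
    preslope_names = c("preslope_total", "preslope_bulbar",
                       "preslope_fine_motor", "preslope_gross_motor"),
    time_name = "days_on_study")
  stopifnot(!anyDuplicated(unlist(sch)))
  class(sch) <- "covariate_schema"
  sch
}

#' Pre-study progression rate from baseline score and onset delta
#'
#' `(max possible score - baseline score) / (days from symptom onset to
#' baseline)`, in points per day. Larger values mean faster pre-study decline.
#'
#' @param baseline_score observed score at baseline.
#' @param max_score maximum possible value of that score (48 for the ALSFRS-R
#'   total, 12 for a domain subscore).
#' @param onset_to_baseline days from symptom onset to baseline, > 0.
#' @return points per day (vectorized).
#' @export
compute_preslope <- function(baseline_score, max_score, onset_to_baseline) {
  if (any(onset_to_baseline <= 0)) {
    stop("onset_to_baseline must be > 0", call. = FALSE)
  }
  if (any(baseline_score < 0) || any(baseline_score > max_score)) {
    stop("baseline_score must lie in [0, max_score]", call. = FALSE)
  }
  (max_score - baseline_score) / onset_to_baseline
}

# Add the four derived preslopes to a baseline table.
add_preslopes <- function(baseline) {
  baseline$preslope_total <- compute_preslope(baseline$baseline_frs, 48,
                                              baseline$onset_delta_days)
  baseline$preslope_bulbar <- compute_preslope(baseline$sub_bulbar, 12,
                                               baseline$onset_delta_days)
  baseline$preslope_fine_motor <- compute_preslope(baseline$sub_fine_motor, 12,
                                                   baseline$onset_delta_days)
  baseline$preslope_gross_motor <- compute_preslope(baseline$sub_gross_motor, 12,
                                                    baseline$onset_delta_days)
  baseline
}

#' Build the predictor feature table from a longitudinal dataset
#'
#' Expands baseline covariates against post-baseline (and optionally baseline)
#' visits: one row per patient-visit, with `days_on_study` and the full
#' candidate-covariate schema, plus the observed ALSFRS-R as `outcome`.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param schema a [covariate_schema()].
#' @param include_baseline_rows keep day-0 rows (default FALSE: predictors
#'   model post-baseline scores).
#' @return list with `features` (data.frame), `outcome` (numeric vector) and
#'   `patient_id` (for grouped cross-validation).
#' @export
build_feature_table <- function(dataset, schema = covariate_schema(),
                                include_baseline_rows = FALSE) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  bl <- add_preslopes(dataset$baseline)
  v <- dataset$visits
  if (!include_baseline_rows) v <- v[v$day > 0, , drop = FALSE]
  idx <- match(v$patient_id, bl$patient_id)
  if (anyNA(idx)) stop("visit rows without a baseline record", call. = FALSE)
  cols <- c(schema$demographic_names, schema$score_names, schema$preslope_names)
  feat <- bl[idx, cols, drop = FALSE]
  feat[[schema$time_name]] <- v$day
  rownames(feat) <- NULL
  list(features = feat, outcome = as.numeric(v$alsfrs_r),
       patient_id = v$patient_id)
}

#' Random-forest configuration
#'
#' @param n_trees number of trees (default 500).
#' @param mtry candidate variables per split.
#' @param seed integer seed.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, mtry = NULL, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)), class = "rf_config")
}

# Out-of-bag predictions from per-tree predictions and inbag counts.
# Rows that are in-bag for every tree yield NA and are excluded from the MSE.
oob_from_trees <- function(tree_preds, inbag) {
  oob_mask <- inbag == 0L
  n_oob <- rowSums(oob_mask)
  pred <- rowSums(tree_preds * oob_mask) / pmax(n_oob, 1L)
  pred[n_oob == 0L] <- NA_real_
  pred
}

#' Out-of-bag mean squared error of a fitted random forest
#'
#' Recomputes the OOB error from the stored per-tree bootstrap masks: each
#' observation is predicted by averaging only the trees whose bootstrap
#' sample excluded it.
#'
#' @param fit an `rf_model` from [fit_rf()].
#' @return OOB mean squared error.
#' @export
rf_oob_error <- function(fit) {
  stopifnot(inherits(fit, "rf_model"))
  tp <- stats::predict(fit$forest, data = fit$train_x, predict.all = TRUE,
                       num.threads = 1L)$predictions
  inbag <- do.call(cbind, fit$forest$inbag.counts)
  pred <- oob_from_trees(tp, inbag)
  ok <- !is.na(pred)
  mean((fit$train_y[ok] - pred[ok])^2)
}

#' Tune the number of variables per split by out-of-bag error
#'
#' Fits one forest per candidate `mtry` at fixed tree count and seed and
#' returns the candidate with minimal OOB mean squared error; ties break
#' toward the smaller value.
#'
#' @param features data.frame of covariates (no missing cells).
#' @param outcome numeric vector.
#' @param config an [rf_config()].
#' @param candidates integer candidates, each in `[1, #features]`.
#' @return list with `mtry` (selected) and `oob_errors` (named per candidate).
#' @export
tune_rf_mtry <- function(features, outcome, config = rf_config(),
                         candidates = c(2, 4, 6, 8, 10, 12)) {
  if (!length(candidates)) stop("candidates must be non-empty", call. = FALSE)
  if (length(outcome) != nrow(features)) stop("outcome length mismatch", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  p <- ncol(encode_features(features)$x)
  candidates <- candidates[candidates >= 1 & candidates <= p]
  if (!length(candidates)) stop("no candidate mtry within [1, #features]", call. = FALSE)
  errs <- vapply(candidates, function(m) {
    cfg <- config; cfg$mtry <- m
    rf_oob_error(fit_rf(features, outcome, cfg))
  }, numeric(1L))
  names(errs) <- candidates
  list(mtry = candidates[which.min(errs)], oob_errors = errs)
}

#' Fit the random-forest ALSFRS-R predictor
#'
#' @param features data.frame of covariates (mixed types allowed; no missing
#'   cells — impute first).
#' @param outcome numeric ALSFRS-R scores.
#' @param config an [rf_config()].
#' @return an `rf_model` with a `predict()` method; carries the encoder, the
#'   per-tree bootstrap masks, and the self-computed OOB mean squared error.
#' @export
fit_rf <- function(features, outcome, config = rf_config()) {
  stopifnot(is.data.frame(features))
  if (anyNA(features)) {
    stop("features contain missing cells; run missforest_impute() first",
         call. = FALSE)
  }
  if (length(outcome) != nrow(features)) stop("outcome length mismatch", call. = FALSE)
  enc <- encode_features(features)
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(enc$x))))
  if (mtry < 1 || mtry > ncol(enc$x)) stop("mtry out of range", call. = FALSE)
  forest <- ranger::ranger(x = enc$x, y = outcome, num.trees = config$n_trees,
                           mtry = mtry, keep.inbag = TRUE, num.threads = 1L,
                           seed = config$seed)
  fit <- structure(list(forest = forest, encoder = enc$encoder,
                        config = config, train_x = enc$x, train_y = outcome,
                        feature_names = names(features)),
                   class = "rf_model")
  fit$oob_mse <- rf_oob_error(fit)
  fit
}

#' @export
predict.rf_model <- function(object, baseline, days = NULL, ...) {
  newdf <- prediction_frame(object$feature_names, baseline, days)
  x <- encode_features(newdf, object$encoder)$x
  as.numeric(stats::predict(object$forest, data = x, num.threads = 1L)$predictions)
}

# Assemble a per-row feature frame for prediction: baseline covariates plus a
# days_on_study column. `days` may be a scalar (recycled) or one value per row.
prediction_frame <- function(feature_names, baseline, days) {
  bl <- baseline
  pre_cols <- c("preslope_total", "preslope_bulbar", "preslope_fine_motor",
                "preslope_gross_motor")
  if (any(feature_names %in% pre_cols) && !all(pre_cols %in% names(bl))) {
    bl <- add_preslopes(bl)
  }
  need <- setdiff(feature_names, "days_on_study")
  missing_cols <- setdiff(need, names(bl))
  if (length(missing_cols)) {
    stop("baseline table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- bl[need]
  if ("days_on_study" %in% feature_names) {
    if (is.null(days)) stop("'days' is required", call. = FALSE)
    out$days_on_study <- rep_len(as.numeric(days), nrow(out))
  }
  out
}

#' Predict ALSFRS-R for every patient at each scheduled day
#'
#' @param model a fitted predictor (`rf_model`, `lme_predictor`, or
#'   `superlearner_model`).
#' @param baseline baseline covariate table.
#' @param days vector of days.
#' @return numeric matrix, patients x days.
#' @export
predict_grid <- function(model, baseline, days) {
  out <- vapply(days, function(d) stats::predict(model, baseline, days = d),
                numeric(nrow(baseline)))
  out <- matrix(out, nrow = nrow(baseline))
  colnames(out) <- as.character(days)
  rownames(out) <- baseline$patient_id
  out
}

#' Fit the random-intercept linear mixed model predictor
#'
#' `ALSFRS_ij = b0 + b1 * baseline + b2 * preslope + b3 * day + b4 * age +
#' b5 * onset_delta + u_i + e_ij`, fitted by REML. Predictions for patients
#' not in the training data use the fixed effects only (`u_i = 0`).
#'
#' @param dataset a `longitudinal_dataset` with at least two visits for a
#'   nonzero fraction of patients.
#' @return an `lme_predictor` with coefficients `beta` (length 6),
#'   `sigma_b2` (random-intercept variance), `sigma2` (residual variance),
#'   and the underlying `lme4` fit.
#' @export
fit_lme_predictor <- function(dataset) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  bl <- add_preslopes(dataset$baseline)
  v <- dataset$visits[dataset$visits$day > 0, , drop = FALSE]
  idx <- match(v$patient_id, bl$patient_id)
  df <- data.frame(y = as.numeric(v$alsfrs_r),
                   y0 = as.numeric(bl$baseline_frs[idx]),
                   preslope = bl$preslope_total[idx],
                   day = v$day,
                   age = bl$age[idx],
                   onset_delta = bl$onset_delta_days[idx],
                   pid = v$patient_id)
  nvis <- table(df$pid)
  if (!any(nvis >= 2)) stop("need >= 2 visits for some patients", call. = FALSE)
  for (nm in c("y0", "preslope", "day", "age", "onset_delta")) {
    if (stats::sd(df[[nm]]) < 1e-12) {
      stop(sprintf("singular design: column '%s' is constant", nm), call. = FALSE)
    }
  }
  fit <- lme4::lmer(y ~ y0 + preslope + day + age + onset_delta + (1 | pid),
                    data = df, REML = TRUE)
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(beta = beta,
                 beta_se = stats::setNames(sqrt(diag(as.matrix(stats::vcov(fit)))),
                                           names(beta)),
                 sigma_b2 = vc$vcov[vc$grp == "pid"],
                 sigma2 = vc$vcov[vc$grp == "Residual"],
                 fit = fit),
            class = "lme_predictor")
}

#' @export
predict.lme_predictor <- function(object, baseline, days = NULL, ...) {
  if (is.null(days)) stop("'days' is required", call. = FALSE)
  bl <- add_preslopes(baseline)
  b <- object$beta
  as.numeric(b[["(Intercept)"]] +
               b[["y0"]] * bl$baseline_frs +
               b[["preslope"]] * bl$preslope_total +
               b[["day"]] * rep_len(as.numeric(days), nrow(bl)) +
               b[["age"]] * bl$age +
               b[["onset_delta"]] * bl$onset_delta_days)
}

# ---- super learner ---------------------------------------------------------

#' Default super-learner base library
#'
#' Four base learners: gradient-boosted trees (xgboost), ordinary linear
#' regression, a random forest, and an elastic-net linear model
#' (`glmnet`, alpha = 0.5, lambda by internal 5-fold CV). Each learner is a
#' list with `name`, `fit(x, y, seed)` and `predict(fit, x)` operating on the
#' numeric encoded feature matrix.
#'
#' @param rf_trees trees for the base random forest (default 150; the
#'   standalone predictor in [fit_rf()] keeps 500).
#' @param xgb_rounds boosting rounds (default 150).
#' @return list of learners.
#' @export
default_learners <- function(rf_trees = 150, xgb_rounds = 150) {
  list(
    list(name = "xgboost",
         fit = function(x, y, seed) {
           d <- xgboost::xgb.DMatrix(data = x, label = y)
           set.seed(seed)
           xgboost::xgb.train(params = list(max_depth = 4, eta = 0.1,
                                            subsample = 0.8,
                                            objective = "reg:squarederror",
                                            nthread = 1L),
                              data = d, nrounds = xgb_rounds)
         },
         predict = function(fit, x) as.numeric(stats::predict(fit, x))),
    list(name = "linear",
         fit = function(x, y, seed) {
           stats::lm.fit(cbind(1, x), y)$coefficients
         },
         predict = function(fit, x) {
           co <- fit; co[is.na(co)] <- 0
           as.numeric(cbind(1, x) %*% co)
         }),
    list(name = "random_forest",
         fit = function(x, y, seed) {
           ranger::ranger(x = x, y = y, num.trees = rf_trees,
                          num.threads = 1L, seed = seed)
         },
         predict = function(fit, x) {
           as.numeric(stats::predict(fit, data = x, num.threads = 1L)$predictions)
         }),
    list(name = "elastic_net",
         fit = function(x, y, seed) {
           set.seed(seed)
           glmnet::cv.glmnet(x, y, alpha = 0.5, nfolds = 5)
         },
         predict = function(fit, x) {
           as.numeric(stats::predict(fit, newx = x, s = "lambda.min"))
         })
  )
}

# Exact argmin of ||y - Z w||^2 over the probability simplex, by active-set
# enumeration over learner subsets (K is small). Singular KKT systems use the
# minimum-norm solution, which splits weight equally among duplicated
# learners.
simplex_weights <- function(Z, y) {
  K <- ncol(Z)
  best <- NULL
  best_risk <- Inf
  for (mask in seq_len(2^K - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(K) - 1L)) > 0L)
    Zs <- Z[, S, drop = FALSE]
    ks <- length(S)
    # KKT system for min ||y - Zs w||^2 s.t. sum(w) = 1
    A <- rbind(cbind(2 * crossprod(Zs), rep(1, ks)), c(rep(1, ks), 0))
    bvec <- c(2 * crossprod(Zs, y), 1)
    sol <- tryCatch(solve(A, bvec), error = function(e) {
      as.numeric(MASS::ginv(A) %*% bvec)
    })
    w <- sol[seq_len(ks)]
    if (any(w < -1e-10)) next
    w <- pmax(w, 0); w <- w / sum(w)
    risk <- mean((y - Zs %*% w)^2)
    if (risk < best_risk - 1e-12) {
      best_risk <- risk
      best <- numeric(K); best[S] <- w
    }
  }
  if (is.null(best)) {  # fall back to the best single learner
    risks <- colMeans((y - Z)^2)
    best <- numeric(K); best[which.min(risks)] <- 1
  }
  best
}

#' Fit the super learner
#'
#' Out-of-fold predictions for each base learner are assembled over `k_folds`
#' cross-validation folds; the stacking weights are the exact minimizer of
#' the out-of-fold mean squared error over the probability simplex
#' (non-negative, summing to one). Learners with positive weight are refit on
#' the full data; a learner that fails on any fold gets weight zero with a
#' warning.
#'
#' @param features data.frame of covariates (no missing cells).
#' @param outcome numeric vector.
#' @param k_folds folds for weight tuning (default 10).
#' @param seed integer seed.
#' @param learners base library, see [default_learners()].
#' @param group optional grouping vector (e.g. patient id); when given, folds
#'   are assigned by group so a patient's visits never straddle a fold.
#' @return a `superlearner_model` with `weights`, `cv_risk` per learner, the
#'   out-of-fold prediction matrix, and the refit base learners.
#' @export
fit_superlearner <- function(features, outcome, k_folds = 10, seed = 1L,
                             learners = default_learners(), group = NULL) {
  stopifnot(is.data.frame(features))
  n <- nrow(features)
  if (length(outcome) != n) stop("outcome length mismatch", call. = FALSE)
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  if (n < k_folds) stop("need n >= k_folds", call. = FALSE)
  if (anyNA(features)) stop("features contain missing cells", call. = FALSE)
  enc <- encode_features(features)
  x <- enc$x
  K <- length(learners)

  run_seeded(seed, {
    if (is.null(group)) {
      fold <- sample(rep_len(seq_len(k_folds), n))
    } else {
      g <- unique(group)
      gf <- stats::setNames(sample(rep_len(seq_len(k_folds), length(g))), g)
      fold <- gf[as.character(group)]
    }
    Z <- matrix(NA_real_, n, K)
    colnames(Z) <- vapply(learners, `[[`, character(1L), "name")
    failed <- logical(K)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      for (k in seq_len(K)) {
        if (failed[k]) next
        lseed <- as.integer(child_seed(seed, f * 100L + k))
        res <- tryCatch({
          fit <- learners[[k]]$fit(x[tr, , drop = FALSE], outcome[tr], lseed)
          learners[[k]]$predict(fit, x[!tr, , drop = FALSE])
        }, error = function(e) e)
        if (inherits(res, "error") || anyNA(res)) {
          warning(sprintf("base learner '%s' failed on fold %d; weight forced to 0",
                          colnames(Z)[k], f))
          failed[k] <- TRUE
        } else {
          Z[!tr, k] <- res
        }
      }
    }
    ok <- which(!failed)
    if (!length(ok)) stop("every base learner failed", call. = FALSE)
    w <- numeric(K)
    w[ok] <- simplex_weights(Z[, ok, drop = FALSE], outcome)
    cv_risk <- rep(NA_real_, K)
    cv_risk[ok] <- colMeans((outcome - Z[, ok, drop = FALSE])^2)
    names(cv_risk) <- colnames(Z)

    fits <- vector("list", K)
    for (k in ok) {
      if (w[k] > 0) {
        fits[[k]] <- learners[[k]]$fit(x, outcome,
                                       as.integer(child_seed(seed, 9000L + k)))
      }
    }
    structure(list(weights = stats::setNames(w, colnames(Z)),
                   cv_risk = cv_risk, folds = unname(fold),
                   oof_predictions = Z, oof_risk = mean((outcome - Z[, ok, drop = FALSE] %*% w[ok])^2),
                   learners = learners, fits = fits,
                   encoder = enc$encoder, feature_names = names(features)),
              class = "superlearner_model")
  })
}

#' @export
predict.superlearner_model <- function(object, baseline, days = NULL, ...) {
  newdf <- prediction_frame(object$feature_names, baseline, days)
  x <- encode_features(newdf, object$encoder)$x
  out <- numeric(nrow(x))
  for (k in seq_along(object$fits)) {
    if (!is.null(object$fits[[k]]) && object$weights[k] > 0) {
      out <- out + object$weights[k] *
        object$learners[[k]]$predict(object$fits[[k]], x)
    }
  }
  out
}

#' @export
print.superlearner_model <- function(x, ...) {
  cat("Super learner: stacking weights\n")
  print(round(x$weights, 4))
  cat("Out-of-fold MSE per learner:\n")
  print(round(x$cv_risk, 3))
  invisible(x)
}
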