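#' Trial simulation engine
#'
#' Simulated trials are built by resampling patients from a trial pool
#' without replacement, randomizing them 1:1 to active or placebo, and
#' injecting a hypothetical treatment effect of size `E` by shrinking the
#' active arm's change from baseline: `Y_trt = Y0 + (Y - Y0) * (1 - E)`.
#' `E = 0` leaves outcomes bit-identical; placebo records are never touched.
#'
#' @name trialsim
NULL

#' Visit schedule for a study duration
#'
#' 6-month studies visit at months 0, 1, 2, 3, 6; 12-month studies at months
#' 0, 1, 6, 12; 18-month studies at months 0, 1, 6, 12, 18. Days are months
#' times 30.44, rounded.
#'
#' @param duration_months 6, 12, or 18.
#' @return a `visit_schedule` with `duration_months`, `visit_months`, `days`.
#' @export
visit_schedule <- function(duration_months) {
  months <- switch(as.character(duration_months),
                   "6" = c(0, 1, 2, 3, 6),
                   "12" = c(0, 1, 6, 12),
                   "18" = c(0, 1, 6, 12, 18),
                   stop("duration_months must be 6, 12, or 18", call. = FALSE))
  structure(list(duration_months = duration_months, visit_months = months,
                 days = round(months * DAYS_PER_MONTH)),
            class = "visit_schedule")
}

#' Trial simulation configuration
#'
#' @param duration_months study duration (6, 12, or 18).
#' @param n_total total enrollment (even, split 1:1).
#' @param effect_e shrinkage fraction of change from baseline in `[0, 1)`.
#' @param n_replicates number of simulated trials.
#' @param master_seed integer; replicate seeds are derived as master + index.
#' @return a `trial_config`.
#' @export
trial_config <- function(duration_months = 12, n_total = 200, effect_e = 0,
                         n_replicates = 2000, master_seed = 1L) {
  if (n_total < 2 || n_total %% 2 != 0) {
    stop("n_total must be an even count >= 2", call. = FALSE)
  }
  if (effect_e < 0 || effect_e >= 1) stop("effect_e must be in [0, 1)", call. = FALSE)
  structure(list(schedule = visit_schedule(duration_months),
                 duration_months = duration_months,
                 n_total = as.integer(n_total), effect_e = effect_e,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "trial_config")
}

#' Shrink change from baseline by the hypothetical treatment effect
#'
#' @param y_baseline baseline score(s).
#' @param y_observed observed post-baseline score(s).
#' @param effect_e shrinkage fraction in `[0, 1)`.
#' @return `y_baseline + (y_observed - y_baseline) * (1 - effect_e)`.
#' @export
apply_treatment_effect <- function(y_baseline, y_observed, effect_e) {
  if (any(effect_e < 0) || any(effect_e >= 1)) {
    stop("effect_e must be in [0, 1)", call. = FALSE)
  }
  y_baseline + (y_observed - y_baseline) * (1 - effect_e)
}

# Precompute the pool's outcome arrays on a schedule: baseline vector and a
# patients x post-visits matrix, matching scheduled days to pool visit days
# within +/- `window` days (nearest wins; unmatched visits are NA and the
# MMRM handles them by likelihood).
pool_arrays <- function(pool, schedule, window = 15) {
  stopifnot(inherits(pool, "longitudinal_dataset"))
  ids <- pool$baseline$patient_id
  n <- length(ids)
  days <- sort(unique(pool$visits$day))
  wide <- matrix(NA_real_, n, length(days),
                 dimnames = list(ids, as.character(days)))
  ridx <- match(pool$visits$patient_id, ids)
  cidx <- match(pool$visits$day, days)
  wide[cbind(ridx, cidx)] <- pool$visits$alsfrs_r
  sched <- schedule$days
  post <- sched[sched > 0]
  y0col <- which(days == 0)
  if (!length(y0col)) stop("pool has no day-0 visits", call. = FALSE)
  y0 <- wide[, y0col]
  if (anyNA(y0)) stop("some pool patients lack a baseline visit", call. = FALSE)
  ypost <- matrix(NA_real_, n, length(post),
                  dimnames = list(ids, as.character(post)))
  for (j in seq_along(post)) {
    cand <- which(abs(days - post[j]) <= window & days > 0)
    cand <- cand[order(abs(days[cand] - post[j]))]
    for (cc in cand) {
      fill <- is.na(ypost[, j]) & !is.na(wide[, cc])
      ypost[fill, j] <- wide[fill, cc]
    }
  }
  list(ids = ids, y0 = y0, ypost = ypost, post_days = post)
}

#' Sample one simulated trial replicate
#'
#' Draws `n_total` distinct patients from the pool, randomizes the sampled
#' order 1:1 (first half active), and shrinks active-arm change from baseline
#' by `effect_e`. Scheduled visits are matched to pool visit days within a
#' 15-day window; a patient missing a scheduled visit contributes a missing
#' outcome there.
#'
#' @param pool a `longitudinal_dataset` trial pool.
#' @param config a [trial_config()].
#' @param replicate_seed integer seed for this replicate.
#' @return a `trial_replicate` with `patients` (id, arm), `baseline`
#'   (covariate rows), `y0`, `y_observed` and `y_change` (patients x visits,
#'   effect-adjusted), `post_days`, `pool_index`, and a long `visits` table.
#' @export
sample_trial <- function(pool, config, replicate_seed = config$master_seed) {
  arr <- pool_arrays(pool, config$schedule)
  sample_trial_fast(pool, arr, config, replicate_seed)
}

# Internal work-horse shared with run_replicates(): takes precomputed arrays.
sample_trial_fast <- function(pool, arr, config, replicate_seed) {
  n_pool <- length(arr$ids)
  n <- config$n_total
  if (n_pool < n) {
    stop(sprintf("pool has %d patients; cannot draw %d without replacement",
                 n_pool, n), call. = FALSE)
  }
  idx <- run_seeded(replicate_seed, sample.int(n_pool, n))
  arm <- rep(c("active", "placebo"), each = n %/% 2L)
  y0 <- arr$y0[idx]
  yobs <- arr$ypost[idx, , drop = FALSE]
  active <- arm == "active"
  yobs[active, ] <- apply_treatment_effect(y0[active], yobs[active, , drop = FALSE],
                                           config$effect_e)
  ychg <- yobs - y0
  J <- length(arr$post_days)
  visits <- data.frame(
    patient_id = c(arr$ids[idx], rep(arr$ids[idx], times = J)),
    day = c(rep(0, n), rep(arr$post_days, each = n)),
    alsfrs_r = c(y0, as.numeric(yobs)))
  visits <- visits[!is.na(visits$alsfrs_r), , drop = FALSE]
  structure(list(replicate_seed = replicate_seed,
                 patients = data.frame(patient_id = arr$ids[idx], arm = arm,
                                       stringsAsFactors = FALSE),
                 baseline = pool$baseline[idx, , drop = FALSE],
                 pool_index = idx,
                 y0 = unname(y0), y_observed = yobs, y_change = ychg,
                 post_days = arr$post_days, visits = visits),
            class = "trial_replicate")
}

#' Run simulated trial replicates and collect treatment p-values
#'
#' For each replicate: sample the trial, randomize, inject the effect, attach
#' model predictions (computed once per pool from baseline covariates and
#' visit day — never from arm or transformed outcomes), fit every requested
#' analysis model, and record the last-visit treatment-interaction p-value.
#' Replicate seeds are `master_seed + replicate index`.
#'
#' @param pool a `longitudinal_dataset` trial pool.
#' @param config a [trial_config()].
#' @param specs list of [analysis_spec()] objects (default: all seven).
#' @param models optional named list of fitted predictors (`rf`, `lme`, `sl`)
#'   used to compute pool-level prediction matrices.
#' @param predictions optional named list of precomputed pool-aligned
#'   prediction matrices (patients x post-baseline visits); overrides
#'   `models`.
#' @return a `replicate_pvalues` object: list with `p_values` (replicates x
#'   specs matrix, NA for failed fits), `n_nonconverged` per spec, `config`.
#' @export
run_replicates <- function(pool, config, specs = analysis_specs(),
                           models = NULL, predictions = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (inherits(specs, "analysis_spec")) specs <- list(specs)
  spec_names <- vapply(specs, `[[`, character(1L), "name")
  names(specs) <- spec_names
  arr <- pool_arrays(pool, config$schedule)

  needed <- unique(unlist(lapply(specs, function(s) s$extras$prediction)))
  if (length(needed) && is.null(predictions)) {
    if (is.null(models)) {
      stop("prediction specs need 'models' or 'predictions'", call. = FALSE)
    }
    predictions <- lapply(stats::setNames(needed, needed), function(key) {
      if (is.null(models[[key]])) {
        stop(sprintf("no fitted model supplied for '%s'", key), call. = FALSE)
      }
      predict_grid(models[[key]], pool$baseline, arr$post_days)
    })
  }

  R <- config$n_replicates
  pmat <- matrix(NA_real_, R, length(specs),
                 dimnames = list(NULL, spec_names))
  nonconv <- stats::setNames(integer(length(specs)), spec_names)
  for (r in seq_len(R)) {
    rep_seed <- child_seed(config$master_seed, r)
    trial <- sample_trial_fast(pool, arr, config, rep_seed)
    preds_rep <- if (!is.null(predictions)) {
      lapply(predictions, function(m) m[trial$pool_index, , drop = FALSE])
    }
    for (s in seq_along(specs)) {
      des <- build_design(trial, specs[[s]], predictions = preds_rep)
      fit <- fit_mmrm(des)
      pv <- treatment_pvalue(fit)
      if (is.na(pv)) nonconv[s] <- nonconv[s] + 1L
      pmat[r, s] <- pv
    }
  }
  structure(list(p_values = pmat, n_nonconverged = nonconv, config = config),
            class = "replicate_pvalues")
}

#' @export
print.replicate_pvalues <- function(x, ...) {
  cat(sprintf("Simulated trials: %d replicates, %d-month schedule, n = %d, E = %.0f%%\n",
              nrow(x$p_values), x$config$duration_months, x$config$n_total,
              100 * x$config$effect_e))
  cat("Rejection rate at alpha = 0.05:\n")
  print(round(colMeans(x$p_values < 0.05, na.rm = TRUE), 4))
  invisible(x)
}
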