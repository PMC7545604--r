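#' Validation protocol: MSPE and observed-on-predicted regression diagnostics
#'
#' Model fit is summarized by the mean squared prediction error and by a
#' simple linear regression of the observed ALSFRS-R on the predicted value:
#' the regression R-squared measures the variation of the observed explained
#' by the predictions, the intercept measures bias (with a two-sided t-test),
#' and the slope measures calibration. The same machinery runs on the total
#' score, on the change-from-baseline scale, and stratified by month.
#'
#' @name validate
NULL

#' Prediction accuracy metrics
#'
#' @param observed,predicted numeric vectors of equal length (>= 3 for the
#'   regression fields).
#' @return a `validation_report`: list with `mspe`, `r2`, `intercept`,
#'   `intercept_p`, `slope`, `n`. When the predictions are constant the
#'   regression is undefined: `mspe` is still returned and the regression
#'   fields are `NA` with `degenerate = TRUE`.
#' @export
prediction_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  mspe <- mean((observed - predicted)^2)
  if (stats::sd(predicted) < 1e-12) {
    rep <- list(mspe = mspe, r2 = NA_real_, intercept = NA_real_,
                intercept_p = NA_real_, slope = NA_real_, n = n,
                degenerate = TRUE)
    class(rep) <- "validation_report"
    return(rep)
  }
  fit <- stats::lm(observed ~ predicted)
  sm <- summary(fit)
  rep <- list(mspe = mspe,
              r2 = sm$r.squared,
              intercept = unname(stats::coef(fit)[1L]),
              intercept_p = sm$coefficients[1L, 4L],
              slope = unname(stats::coef(fit)[2L]),
              n = n, degenerate = FALSE)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("MSPE = %.3f (n = %d); constant predictions, regression undefined\n",
                x$mspe, x$n))
  } else {
    cat(sprintf("MSPE = %.3f, R2 = %.3f, intercept = %.3f (p = %.3g), slope = %.3f (n = %d)\n",
                x$mspe, x$r2, x$intercept, x$intercept_p, x$slope, x$n))
  }
  invisible(x)
}

#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(mspe = x$mspe, r2 = x$r2, intercept = x$intercept,
             intercept_p = x$intercept_p, slope = x$slope, n = x$n)
}

# Align a prediction table (patient_id, day, pred) with post-baseline visits
# and the per-patient baseline score.
align_predictions <- function(dataset, predictions) {
  stopifnot(inherits(dataset, "longitudinal_dataset"),
            all(c("patient_id", "day", "pred") %in% names(predictions)))
  v <- dataset$visits
  base <- v[v$day == 0, ]
  y0 <- stats::setNames(base$alsfrs_r, base$patient_id)
  post <- v[v$day > 0, , drop = FALSE]
  if (anyNA(y0[post$patient_id])) stop("missing baseline row", call. = FALSE)
  key <- paste(post$patient_id, post$day)
  pkey <- paste(predictions$patient_id, predictions$day)
  idx <- match(key, pkey)
  if (anyNA(idx)) stop("predictions missing for some visits", call. = FALSE)
  data.frame(patient_id = post$patient_id, day = post$day,
             observed = as.numeric(post$alsfrs_r),
             predicted = predictions$pred[idx],
             y0 = as.numeric(y0[post$patient_id]))
}

#' Metrics on the change-from-baseline scale
#'
#' Computes [prediction_metrics()] on `(Y_ij - Y_i0)` versus
#' `(pred_ij - Y_i0)`, excluding day-0 rows. The MSPE is algebraically equal
#' to the total-score MSPE; the regression diagnostics differ.
#'
#' @param dataset a `longitudinal_dataset` with a day-0 row per patient.
#' @param predictions data.frame `patient_id, day, pred` covering every
#'   post-baseline visit.
#' @return a `validation_report`.
#' @export
change_metrics <- function(dataset, predictions) {
  al <- align_predictions(dataset, predictions)
  prediction_metrics(al$observed - al$y0, al$predicted - al$y0)
}

#' Total-score metrics for a dataset/prediction pair
#'
#' @inheritParams change_metrics
#' @return a `validation_report`.
#' @export
total_metrics <- function(dataset, predictions) {
  al <- align_predictions(dataset, predictions)
  prediction_metrics(al$observed, al$predicted)
}

#' Validation metrics stratified by month on study
#'
#' Visits are binned by `day / 30.44` into right-open month bins; one report
#' is produced per non-empty bin, and bins with fewer than 3 points are
#' skipped with a message.
#'
#' @inheritParams change_metrics
#' @param month_edges sorted bin edges in months (right-open bins).
#' @return data.frame with one row per retained bin: `month_bin` (left edge)
#'   plus the `validation_report` fields.
#' @export
metrics_by_month <- function(dataset, predictions,
                             month_edges = c(0, 2, 4, 7, 10, 13, 16, 19)) {
  if (is.unsorted(month_edges, strictly = TRUE)) {
    stop("month_edges must be sorted", call. = FALSE)
  }
  al <- align_predictions(dataset, predictions)
  months <- al$day / DAYS_PER_MONTH
  bin <- cut(months, breaks = month_edges, right = FALSE,
             labels = month_edges[-length(month_edges)])
  out <- list()
  for (lv in levels(bin)) {
    sel <- which(!is.na(bin) & bin == lv)
    if (!length(sel)) next
    if (length(sel) < 3L) {
      message(sprintf("month bin %s skipped: only %d point(s)", lv, length(sel)))
      next
    }
    rep <- prediction_metrics(al$observed[sel], al$predicted[sel])
    out[[lv]] <- cbind(data.frame(month_bin = as.numeric(lv)),
                       as.data.frame(rep))
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a cohort into training and test sets by patient
#'
#' All visits of a patient land on one side, so no within-patient information
#' leaks into the test set.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param test_fraction fraction of patients in the test set (default 0.25).
#' @param seed integer seed.
#' @return list with `train` and `test` `longitudinal_dataset`s.
#' @export
holdout_split <- function(dataset, test_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  ids <- dataset$baseline$patient_id
  if (length(ids) < 2L) stop("need at least 2 patients", call. = FALSE)
  n_test <- max(1L, round(length(ids) * test_fraction))
  run_seeded(seed, {
    test_ids <- sample(ids, n_test)
    subset_ds <- function(keep) {
      ds <- dataset
      ds$baseline <- dataset$baseline[dataset$baseline$patient_id %in% keep, ,
                                      drop = FALSE]
      ds$visits <- dataset$visits[dataset$visits$patient_id %in% keep, ,
                                  drop = FALSE]
      if (!is.null(dataset$latent)) {
        ds$latent <- dataset$latent[dataset$latent$patient_id %in% keep, ,
                                    drop = FALSE]
      }
      rownames(ds$baseline) <- rownames(ds$visits) <- NULL
      ds
    }
    list(train = subset_ds(setdiff(ids, test_ids)),
         test = subset_ds(test_ids))
  })
}
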