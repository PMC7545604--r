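#' Power, type I error, win rates, and effective sample size
#'
#' Aggregates replicate p-values into empirical rejection rates with
#' binomial Monte-Carlo standard errors, win rates (the share of replicates
#' in which a model yields the smallest p-value), and effective-sample-size
#' gains read off interpolated power curves.
#'
#' @name evalpower
NULL

#' Empirical rejection rate
#'
#' @param p_values numeric vector; `NA` entries (non-converged fits) are
#'   dropped.
#' @param alpha significance level (default 0.05).
#' @return list with `power`, `mc_se` (`sqrt(power (1 - power) / n)`), and
#'   `n` (converged replicates used).
#' @export
estimate_power <- function(p_values, alpha = 0.05) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no converged replicates", call. = FALSE)
  pow <- mean(p < alpha)
  list(power = pow, mc_se = sqrt(pow * (1 - pow) / length(p)), n = length(p))
}

#' Win rates: share of replicates with the smallest p-value
#'
#' Rows with any missing p-value are dropped (and counted); ties split the
#' win equally among the tied models.
#'
#' @param p_matrix replicates x models matrix of p-values.
#' @return list with `rates` (named, summing to 1), `n_used`, `n_dropped`.
#' @export
win_rates <- function(p_matrix) {
  stopifnot(is.matrix(p_matrix))
  ok <- stats::complete.cases(p_matrix)
  if (!any(ok)) stop("all replicate rows have missing p-values", call. = FALSE)
  m <- p_matrix[ok, , drop = FALSE]
  wins <- numeric(ncol(m))
  for (r in seq_len(nrow(m))) {
    mn <- min(m[r, ])
    tie <- which(m[r, ] == mn)
    wins[tie] <- wins[tie] + 1 / length(tie)
  }
  rates <- wins / nrow(m)
  names(rates) <- colnames(m)
  list(rates = rates, n_used = nrow(m), n_dropped = sum(!ok))
}

# Isotonic (monotone non-decreasing) smoothing of a power curve on its n-grid.
isotonic_curve <- function(n, power) {
  o <- order(n)
  ir <- stats::isoreg(n[o], power[o])
  list(n = n[o], power = ir$yf)
}

#' Effective-sample-size gain of an adjusted analysis over a reference
#'
#' Both power curves are isotonically smoothed and linearly interpolated on
#' the shared n-grid. The target power is the adjusted curve's value at
#' `n_reference`; `matched_n` is the smallest enrollment at which the
#' reference curve reaches that power. A positive gain means the adjusted
#' analysis needs fewer patients for the same power. No extrapolation: a
#' target outside the reference curve's range is flagged.
#'
#' @param curve_adjusted,curve_reference data.frames with columns `n`,
#'   `power` on the same n-grid.
#' @param n_reference enrollment at which to read the adjusted curve.
#' @return an `ess_result`: list with `n_reference`, `target_power`,
#'   `matched_n`, `gain_patients`, `gain_fraction`, `flagged`.
#' @export
effective_sample_size <- function(curve_adjusted, curve_reference, n_reference) {
  stopifnot(all(c("n", "power") %in% names(curve_adjusted)),
            all(c("n", "power") %in% names(curve_reference)))
  if (!setequal(curve_adjusted$n, curve_reference$n)) {
    stop("curves must share the same n-grid", call. = FALSE)
  }
  adj <- isotonic_curve(curve_adjusted$n, curve_adjusted$power)
  ref <- isotonic_curve(curve_reference$n, curve_reference$power)
  if (n_reference < min(adj$n) || n_reference > max(adj$n)) {
    stop("n_reference outside the simulated n-grid", call. = FALSE)
  }
  target <- stats::approx(adj$n, adj$power, xout = n_reference)$y
  if (target > max(ref$power) || target < min(ref$power)) {
    res <- list(n_reference = n_reference, target_power = target,
                matched_n = NA_real_, gain_patients = NA_real_,
                gain_fraction = NA_real_, flagged = TRUE)
    class(res) <- "ess_result"
    return(res)
  }
  # smallest n where the (monotone) reference curve reaches the target
  above <- which(ref$power >= target)
  j <- min(above)
  matched_n <- if (j == 1L) {
    ref$n[1L]
  } else if (ref$power[j] == ref$power[j - 1L]) {
    ref$n[j]
  } else {
    ref$n[j - 1L] + (target - ref$power[j - 1L]) /
      (ref$power[j] - ref$power[j - 1L]) * (ref$n[j] - ref$n[j - 1L])
  }
  res <- list(n_reference = n_reference, target_power = target,
              matched_n = matched_n,
              gain_patients = matched_n - n_reference,
              gain_fraction = (matched_n - n_reference) / matched_n,
              flagged = FALSE)
  class(res) <- "ess_result"
  res
}

#' @export
print.ess_result <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("ESS: target power %.3f outside the reference curve; no match\n",
                x$target_power))
  } else {
    cat(sprintf(
      "ESS: adjusted power %.3f at n = %d matched by reference at n = %.1f (gain %.1f patients, %.1f%%)\n",
      x$target_power, x$n_reference, x$matched_n, x$gain_patients,
      100 * x$gain_fraction))
  }
  invisible(x)
}

#' Summarize replicate p-values across scenarios
#'
#' @param results list of `replicate_pvalues` objects (one per scenario).
#' @param alpha significance level.
#' @return a `power_summary` data.frame: one row per (spec, n_total,
#'   effect_e, duration) with `power`, `mc_se`, `n_converged`.
#' @export
power_summary <- function(results, alpha = 0.05) {
  rows <- lapply(results, function(res) {
    cfg <- res$config
    do.call(rbind, lapply(colnames(res$p_values), function(sp) {
      est <- estimate_power(res$p_values[, sp], alpha)
      data.frame(spec = sp, n_total = cfg$n_total, effect_e = cfg$effect_e,
                 duration_months = cfg$duration_months,
                 power = est$power, mc_se = est$mc_se, n_converged = est$n)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_summary", "data.frame")
  out
}
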