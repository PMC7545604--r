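#' Missing-data stage: Little's MCAR test and iterative random-forest imputation
#'
#' @name impute
NULL

# EM for the mean and covariance of a multivariate normal with arbitrary
# missingness patterns. Returns ML estimates (mu, sigma) plus the pattern
# bookkeeping reused by the MCAR test.
em_norm <- function(x, tol = 1e-6, max_iter = 200, ridge = 1e-8) {
  stopifnot(is.matrix(x))
  n <- nrow(x); k <- ncol(x)
  obs <- !is.na(x)
  keep <- rowSums(obs) > 0L
  x <- x[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) stop("need at least two rows with any observed value", call. = FALSE)

  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_key)

  mu <- colMeans(x, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  sig <- stats::cov(x, use = "pairwise.complete.obs")
  sig[is.na(sig)] <- 0
  diag(sig)[diag(sig) <= 0] <- 1
  sig <- (sig + t(sig)) / 2

  for (it in seq_len(max_iter)) {
    sx <- numeric(k)
    sxx <- matrix(0, k, k)
    for (rows in pats) {
      o <- obs[rows[1L], ]
      xo <- x[rows, o, drop = FALSE]
      m <- !o
      if (!any(m)) {
        sx <- sx + colSums(x[rows, , drop = FALSE])
        sxx <- sxx + crossprod(x[rows, , drop = FALSE])
        next
      }
      soo <- sig[o, o, drop = FALSE]
      soo_r <- soo + diag(ridge, sum(o))
      B <- solve(soo_r, sig[o, m, drop = FALSE])      # regression of missing on observed
      cm <- sweep(xo, 2L, mu[o]) %*% B                # conditional mean offsets
      xm <- sweep(cm, 2L, mu[m], FUN = "+")
      vcond <- sig[m, m, drop = FALSE] - crossprod(sig[o, m, drop = FALSE], B)
      xf <- matrix(0, length(rows), k)
      xf[, o] <- xo; xf[, m] <- xm
      sx <- sx + colSums(xf)
      cp <- crossprod(xf)
      cp[m, m] <- cp[m, m] + length(rows) * vcond
      sxx <- sxx + cp
    }
    mu_new <- sx / n
    sig_new <- sxx / n - tcrossprod(mu_new)
    sig_new <- (sig_new + t(sig_new)) / 2
    delta <- max(abs(mu_new - mu), abs(sig_new - sig))
    mu <- mu_new; sig <- sig_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = sig, obs = obs, x = x, patterns = pats, n = n, k = k)
}

#' Little's test of missing completely at random
#'
#' Tests whether the missingness pattern of the continuous columns of a
#' baseline table is compatible with MCAR. The grand mean and covariance are
#' estimated by EM under multivariate normality; the statistic is
#' `d2 = sum_p n_p (ybar_obs,p - mu_obs,p)' Sigma_obs,p^-1 (ybar_obs,p -
#' mu_obs,p)` over missingness patterns `p`, compared to a chi-square with
#' `sum_p k_p - k` degrees of freedom. Categorical columns are excluded (the
#' test assumes multivariate normality). Singleton patterns are merged into
#' the nearest pattern (Hamming distance) whose observed set is contained in
#' theirs; singletons with no such target are dropped, with a count.
#'
#' @param table data.frame with at least two numeric columns.
#' @param tol,max_iter EM convergence controls.
#' @return an object of class `mcar_test` with fields `d2`, `df`, `p_value`,
#'   `n_patterns`, `n_dropped`.
#' @export
little_mcar_test <- function(table, tol = 1e-6, max_iter = 200) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1L))
  x <- as.matrix(table[num])
  if (ncol(x) < 2L) stop("need at least two continuous columns", call. = FALSE)
  storage.mode(x) <- "double"

  if (!anyNA(x)) {
    warning("no missing cells: Little's test is degenerate (d2 = 0, p = 1)")
    res <- list(d2 = 0, df = 0L, p_value = 1, n_patterns = 1L, n_dropped = 0L)
    class(res) <- "mcar_test"
    return(res)
  }

  fit <- em_norm(x, tol = tol, max_iter = max_iter)
  obs <- fit$obs; k <- fit$k
  pat_rows <- fit$patterns
  pat_obs <- lapply(pat_rows, function(rows) obs[rows[1L], ])
  sizes <- vapply(pat_rows, length, integer(1L))

  # merge singleton patterns into the nearest pattern whose observed set is a
  # subset of theirs (so the target's mean remains well-defined on its columns)
  n_dropped <- 0L
  if (any(sizes < 2L) && any(sizes >= 2L)) {
    big <- which(sizes >= 2L)
    for (s in which(sizes < 2L)) {
      cand <- big[vapply(big, function(b) all(pat_obs[[b]] <= pat_obs[[s]]) &&
                           any(pat_obs[[b]]), logical(1L))]
      if (!length(cand)) { n_dropped <- n_dropped + sizes[s]; next }
      ham <- vapply(cand, function(b) sum(pat_obs[[b]] != pat_obs[[s]]), integer(1L))
      tgt <- cand[which.min(ham)]
      pat_rows[[tgt]] <- c(pat_rows[[tgt]], pat_rows[[s]])
      sizes[tgt] <- sizes[tgt] + sizes[s]
    }
    keep <- sizes >= 2L
    pat_rows <- pat_rows[keep]; pat_obs <- pat_obs[keep]; sizes <- sizes[keep]
  } else if (all(sizes < 2L)) {
    stop("every missingness pattern has fewer than 2 rows", call. = FALSE)
  }

  d2 <- 0
  df <- 0L
  for (p in seq_along(pat_rows)) {
    o <- pat_obs[[p]]
    rows <- pat_rows[[p]]
    # pooled rows may have extra observed columns; use the target pattern's set
    ybar <- colMeans(fit$x[rows, o, drop = FALSE], na.rm = TRUE)
    diffv <- ybar - fit$mu[o]
    soo <- fit$sigma[o, o, drop = FALSE] + diag(1e-8, sum(o))
    qf <- tryCatch(drop(crossprod(diffv, solve(soo, diffv))),
                   error = function(e) stop(sprintf(
                     "singular covariance sub-block in pattern %d", p), call. = FALSE))
    d2 <- d2 + length(rows) * qf
    df <- df + sum(o)
  }
  df <- df - k
  p_value <- if (df > 0) stats::pchisq(d2, df, lower.tail = FALSE) else 1
  res <- list(d2 = d2, df = df, p_value = p_value,
              n_patterns = length(pat_rows), n_dropped = n_dropped)
  class(res) <- "mcar_test"
  res
}

#' @export
print.mcar_test <- function(x, ...) {
  cat(sprintf("Little's MCAR test: d2 = %.3f, df = %d, p = %.4g (%d patterns)\n",
              x$d2, x$df, x$p_value, x$n_patterns))
  invisible(x)
}

col_mode <- function(v) {
  tab <- table(v)
  names(tab)[which.max(tab)]
}

#' Iterative random-forest imputation for mixed-type baseline tables
#'
#' Implements the missForest algorithm: missing cells are initialized with
#' the column mean (continuous) or mode (categorical); columns are then
#' visited in order of increasing missingness and each is re-imputed by a
#' random forest fitted on the rows where the column is observed, using all
#' other columns (current imputations filled in) as predictors. After each
#' sweep the change statistics
#' `delta_cont = sum((new - old)^2) / sum(new^2)` (continuous imputed cells)
#' and `delta_cat = #changed / #missing` (categorical imputed cells) are
#' computed; for each type, the values from the sweep before that type's
#' first increase are returned, and sweeping stops once every present type
#' has increased or `max_iter` is reached.
#'
#' Observed cells are never altered.
#'
#' @param table data.frame with numeric, factor, character, or logical
#'   columns; `NA` marks a missing cell.
#' @param n_trees trees per forest (default 100).
#' @param mtry variables per split; default `floor(sqrt(p))`.
#' @param max_iter maximum sweeps (default 10).
#' @param seed master seed; per-(sweep, column) seeds are derived from it.
#' @param exclude columns to carry along but never use or impute
#'   (e.g. `patient_id`).
#' @return an `imputation_result`: list with `completed` (the table with no
#'   missing cells), `n_iterations`, `delta_trace` (per-sweep continuous and
#'   categorical change statistics), and `oob_error` (per-variable NRMSE for
#'   continuous, proportion falsely classified for categorical).
#' @export
missforest_impute <- function(table, n_trees = 100, mtry = NULL, max_iter = 10,
                              seed = 1L, exclude = "patient_id") {
  stopifnot(is.data.frame(table))
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  work_cols <- setdiff(names(table), exclude)
  x <- table[work_cols]
  # normalize column types: characters and logicals become factors for ranger
  was_logical <- vapply(x, is.logical, logical(1L))
  for (nm in work_cols) {
    if (is.character(x[[nm]]) || is.logical(x[[nm]])) x[[nm]] <- factor(x[[nm]])
  }
  is_cat <- vapply(x, is.factor, logical(1L))
  miss <- is.na(x)
  n_miss <- colSums(miss)
  if (any(n_miss == nrow(x))) {
    stop("column(s) entirely missing: ",
         paste(work_cols[n_miss == nrow(x)], collapse = ", "), call. = FALSE)
  }

  restore <- function(z) {
    out <- table
    for (nm in work_cols) {
      col <- z[[nm]]
      if (was_logical[[nm]]) col <- as.logical(as.character(col))
      else if (is.factor(col) && is.character(table[[nm]])) col <- as.character(col)
      else if (is.integer(table[[nm]]) && is.numeric(col)) col <- as.integer(round(col))
      out[[nm]] <- col
    }
    out
  }

  if (!any(miss)) {
    res <- list(completed = table, n_iterations = 0L,
                delta_trace = data.frame(iteration = integer(),
                                         delta_continuous = double(),
                                         delta_categorical = double()),
                oob_error = NULL)
    class(res) <- "imputation_result"
    return(res)
  }

  # initial fill: mean / mode
  for (nm in work_cols[n_miss > 0]) {
    if (is_cat[[nm]]) {
      x[[nm]][miss[, nm]] <- col_mode(x[[nm]][!miss[, nm]])
    } else {
      x[[nm]][miss[, nm]] <- mean(x[[nm]][!miss[, nm]])
    }
  }

  order_cols <- work_cols[n_miss > 0][order(n_miss[n_miss > 0])]
  p <- length(work_cols)
  mtry_use <- mtry %||% max(1L, floor(sqrt(p - 1L)))
  has_cont <- any(!is_cat[order_cols])
  has_cat <- any(is_cat[order_cols])

  best_cont <- x; best_cat <- x
  it_best_cont <- 0L; it_best_cat <- 0L
  cont_stopped <- !has_cont; cat_stopped <- !has_cat
  prev_dc <- Inf; prev_dk <- Inf
  trace <- list()
  oob <- stats::setNames(rep(NA_real_, length(order_cols)), order_cols)
  it <- 0L

  while (it < max_iter && !(cont_stopped && cat_stopped)) {
    it <- it + 1L
    x_old <- x
    for (ci in seq_along(order_cols)) {
      nm <- order_cols[ci]
      idx_mis <- miss[, nm]
      obs_rows <- which(!idx_mis)
      preds <- setdiff(work_cols, nm)
      dtrain <- x[obs_rows, preds, drop = FALSE]
      ytrain <- x[[nm]][obs_rows]
      fit <- ranger::ranger(x = dtrain, y = ytrain, num.trees = n_trees,
                            mtry = min(mtry_use, length(preds)),
                            num.threads = 1L,
                            seed = as.integer(child_seed(seed, it * 1000L + ci)),
                            respect.unordered.factors = "order")
      newx <- x[which(idx_mis), preds, drop = FALSE]
      pred <- stats::predict(fit, data = newx, num.threads = 1L)$predictions
      x[[nm]][idx_mis] <- pred
      oob[nm] <- if (is_cat[[nm]]) fit$prediction.error
      else sqrt(fit$prediction.error) / max(stats::sd(ytrain), 1e-12)
    }
    # sweep-level change statistics over imputed cells
    dc <- NA_real_; dk <- NA_real_
    if (has_cont) {
      num <- 0; den <- 0
      for (nm in order_cols[!is_cat[order_cols]]) {
        new <- x[[nm]][miss[, nm]]; old <- x_old[[nm]][miss[, nm]]
        num <- num + sum((new - old)^2); den <- den + sum(new^2)
      }
      dc <- if (den > 0) num / den else 0
    }
    if (has_cat) {
      chg <- 0L; tot <- 0L
      for (nm in order_cols[is_cat[order_cols]]) {
        chg <- chg + sum(x[[nm]][miss[, nm]] != x_old[[nm]][miss[, nm]])
        tot <- tot + sum(miss[, nm])
      }
      dk <- if (tot > 0) chg / tot else 0
    }
    trace[[it]] <- data.frame(iteration = it, delta_continuous = dc,
                              delta_categorical = dk)
    if (has_cont && !cont_stopped) {
      if (dc > prev_dc) cont_stopped <- TRUE
      else { best_cont <- x; prev_dc <- dc; it_best_cont <- it }
    }
    if (has_cat && !cat_stopped) {
      if (dk > prev_dk) cat_stopped <- TRUE
      else { best_cat <- x; prev_dk <- dk; it_best_cat <- it }
    }
  }

  # combine: continuous cells from the pre-increase continuous snapshot,
  # categorical cells from the pre-increase categorical snapshot
  final <- x
  for (nm in order_cols) {
    final[[nm]] <- if (is_cat[[nm]]) best_cat[[nm]] else best_cont[[nm]]
  }
  res <- list(completed = restore(final), n_iterations = it,
              delta_trace = do.call(rbind, trace), oob_error = oob,
              returned_iteration = c(continuous = it_best_cont,
                                     categorical = it_best_cat))
  class(res) <- "imputation_result"
  res
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("missForest-style imputation: %d sweep(s)\n", x$n_iterations))
  if (!is.null(x$oob_error)) {
    cat("OOB error (NRMSE / PFC) per imputed column:\n")
    print(round(x$oob_error, 4))
  }
  invisible(x)
}
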