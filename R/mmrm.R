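#' MMRM analysis models for change from baseline
#'
#' The primary analysis fits, per simulated trial, a marginal linear model
#' for change from baseline with an intercept, the baseline ALSFRS-R,
#' model-specific extra covariates, categorical visit terms, and
#' treatment-by-visit interactions, with an unstructured within-patient
#' residual covariance estimated by restricted maximum likelihood (a mixed
#' model for repeated measures, MMRM). The treatment effect is tested through
#' the interaction at the last scheduled visit.
#'
#' Seven analysis models are compared: three using model predictions as a
#' time-varying covariate (random forest, linear mixed model, super learner),
#' one adjusting for the single best baseline predictor (the total-score
#' preslope), one adjusting for standard stratification factors (site of
#' onset and El Escorial category), one with no extra covariates, and a full
#' model combining the random-forest prediction, the preslope, and the
#' standard factors.
#'
#' @name mmrm
NULL

ANALYSIS_SPEC_NAMES <- c("rf_pred", "lme_pred", "sl_pred",
                         "single_best_predictor", "standard_baseline",
                         "no_extra", "full")

#' Analysis model specification
#'
#' @param name one of `"rf_pred"`, `"lme_pred"`, `"sl_pred"`,
#'   `"single_best_predictor"`, `"standard_baseline"`, `"no_extra"`, `"full"`.
#' @return list of class `analysis_spec` with the extra-covariate layout.
#' @export
analysis_spec <- function(name) {
  name <- match.arg(name, ANALYSIS_SPEC_NAMES)
  extras <- switch(name,
    rf_pred = list(prediction = "rf"),
    lme_pred = list(prediction = "lme"),
    sl_pred = list(prediction = "sl"),
    single_best_predictor = list(baseline = "preslope_total"),
    standard_baseline = list(baseline = c("site_bulbar", "el_definite")),
    no_extra = list(),
    full = list(prediction = "rf",
                baseline = c("preslope_total", "site_bulbar", "el_definite")))
  structure(list(name = name, extras = extras), class = "analysis_spec")
}

#' All seven analysis model specifications
#' @return named list of [analysis_spec()] objects.
#' @export
analysis_specs <- function() {
  stats::setNames(lapply(ANALYSIS_SPEC_NAMES, analysis_spec), ANALYSIS_SPEC_NAMES)
}

# Baseline covariates the specs may reference, derived from a baseline table.
spec_baseline_covariates <- function(baseline) {
  bl <- add_preslopes(baseline)
  data.frame(preslope_total = bl$preslope_total,
             site_bulbar = as.numeric(bl$site_of_onset == "bulbar"),
             el_definite = as.numeric(bl$el_escorial == "definite"))
}

#' Build the MMRM design for one trial replicate and one analysis model
#'
#' The outcome is change from baseline at each post-baseline visit. Columns:
#' intercept, baseline ALSFRS-R, the spec's extra covariates (the prediction
#' covariate is time-varying: its value differs by visit), visit indicator
#' terms (reference = first post-baseline visit), and one treatment-by-visit
#' interaction per post-baseline visit.
#'
#' @param replicate a `trial_replicate` from [sample_trial()].
#' @param spec an [analysis_spec()].
#' @param predictions named list of prediction matrices (patients x visits,
#'   aligned with `replicate$patients`), keyed `rf`, `lme`, `sl`; required for
#'   prediction specs.
#' @param include_baseline keep the baseline-ALSFRS-R column (default TRUE;
#'   FALSE gives the saturated cell-means layout used by oracle checks).
#' @return an `mmrm_design`: list with `y` (n x J change matrix, NA = missing
#'   visit), `x` (list of J per-visit design matrices sharing `columns`),
#'   `arm`, `patient_id`, `visit_days`.
#' @export
build_design <- function(replicate, spec, predictions = NULL,
                         include_baseline = TRUE) {
  stopifnot(inherits(replicate, "trial_replicate"), inherits(spec, "analysis_spec"))
  n <- nrow(replicate$patients)
  J <- length(replicate$post_days)
  ychg <- replicate$y_change
  trt <- as.numeric(replicate$patients$arm == "active")

  pred_mat <- NULL
  if (!is.null(spec$extras$prediction)) {
    key <- spec$extras$prediction
    if (is.null(predictions[[key]])) {
      stop(sprintf("spec '%s' needs predictions[['%s']]", spec$name, key),
           call. = FALSE)
    }
    pred_mat <- predictions[[key]]
    stopifnot(nrow(pred_mat) == n, ncol(pred_mat) == J)
  }
  bl_cov <- NULL
  if (!is.null(spec$extras$baseline)) {
    bc <- spec_baseline_covariates(replicate$baseline)
    bl_cov <- as.matrix(bc[, spec$extras$baseline, drop = FALSE])
  }

  base_cols <- c("intercept", if (include_baseline) "y0")
  extra_cols <- c(if (!is.null(pred_mat)) "pred",
                  if (!is.null(bl_cov)) colnames(bl_cov))
  visit_cols <- if (J > 1L) paste0("visit", 2:J)
  int_cols <- paste0("trt_visit", 1:J)
  columns <- c(base_cols, extra_cols, visit_cols, int_cols)

  x <- vector("list", J)
  for (j in seq_len(J)) {
    mats <- list(intercept = rep(1, n))
    if (include_baseline) mats$y0 <- replicate$y0
    if (!is.null(pred_mat)) mats$pred <- pred_mat[, j]
    if (!is.null(bl_cov)) for (nm in colnames(bl_cov)) mats[[nm]] <- bl_cov[, nm]
    if (J > 1L) for (t in 2:J) mats[[paste0("visit", t)]] <- rep(as.numeric(j == t), n)
    for (t in 1:J) mats[[paste0("trt_visit", t)]] <- as.numeric(j == t) * trt
    xj <- do.call(cbind, mats)
    colnames(xj) <- columns
    x[[j]] <- xj
  }
  structure(list(y = ychg, x = x, columns = columns, arm = replicate$patients$arm,
                 patient_id = replicate$patients$patient_id,
                 visit_days = replicate$post_days),
            class = "mmrm_design")
}

# ---- REML fitting ----------------------------------------------------------

# EM-REML for the marginal model y_i ~ N(X_i beta, Sigma) with complete data.
# Per-visit cross-products are precomputed once, so each iteration costs
# O(J^2 p^2) plus one residual pass.
mmrm_em <- function(y, x, structure = c("unstructured", "compound_symmetry"),
                    tol = 1e-10, max_iter = 500) {
  structure <- match.arg(structure)
  n <- nrow(y); J <- ncol(y); p <- ncol(x[[1L]])
  xtx <- vector("list", J * J)
  xty <- vector("list", J * J)
  for (j in seq_len(J)) for (k in seq_len(J)) {
    xtx[[(j - 1L) * J + k]] <- crossprod(x[[j]], x[[k]])
    xty[[(j - 1L) * J + k]] <- crossprod(x[[j]], y[, k])
  }
  sigma <- diag(pmax(apply(y, 2L, stats::var), 1e-8), J)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- tryCatch(solve(sigma), error = function(e) NULL)
    if (is.null(w)) break
    xtwx <- matrix(0, p, p); xtwy <- numeric(p)
    for (j in seq_len(J)) for (k in seq_len(J)) {
      wjk <- w[j, k]
      if (wjk == 0) next
      xtwx <- xtwx + wjk * xtx[[(j - 1L) * J + k]]
      xtwy <- xtwy + wjk * xty[[(j - 1L) * J + k]]
    }
    ch <- tryCatch(chol(xtwx), error = function(e) NULL)
    if (is.null(ch)) break
    beta <- drop(backsolve(ch, forwardsolve(t(ch), xtwy)))
    cmat <- chol2inv(ch)
    r <- y
    for (j in seq_len(J)) r[, j] <- y[, j] - drop(x[[j]] %*% beta)
    tmat <- matrix(0, J, J)
    xc <- lapply(x, function(xj) xj %*% cmat)
    for (j in seq_len(J)) for (k in j:J) {
      tjk <- sum(xc[[j]] * x[[k]])
      tmat[j, k] <- tjk; tmat[k, j] <- tjk
    }
    sigma_new <- (crossprod(r) + tmat) / n
    if (structure == "compound_symmetry" && J > 1L) {
      s2 <- mean(diag(sigma_new))
      rho <- mean(sigma_new[upper.tri(sigma_new)]) / s2
      rho <- min(max(rho, -1 / (J - 1) + 1e-6), 1 - 1e-6)
      sigma_new <- s2 * ((1 - rho) * diag(J) + rho * matrix(1, J, J))
    }
    delta <- max(abs(sigma_new - sigma)) / max(max(abs(sigma)), 1e-12)
    sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) return(NULL)
  # final GLS pass at the converged covariance
  w <- solve(sigma)
  xtwx <- matrix(0, p, p); xtwy <- numeric(p)
  for (j in seq_len(J)) for (k in seq_len(J)) {
    xtwx <- xtwx + w[j, k] * xtx[[(j - 1L) * J + k]]
    xtwy <- xtwy + w[j, k] * xty[[(j - 1L) * J + k]]
  }
  cmat <- solve(xtwx)
  beta <- drop(cmat %*% xtwy)
  list(beta = beta, vcov = cmat, sigma = sigma, n_iter = it)
}

# Exact-REML path for incomplete visit data, via generalized least squares
# with a general correlation matrix and per-visit variances.
mmrm_gls <- function(y, x, columns, structure = "unstructured") {
  n <- nrow(y); J <- ncol(y)
  rows <- list()
  for (j in seq_len(J)) {
    ok <- which(!is.na(y[, j]))
    if (!length(ok)) next
    d <- as.data.frame(x[[j]][ok, , drop = FALSE])
    names(d) <- paste0("c", seq_along(columns))
    d$.y <- y[ok, j]; d$.visit <- j; d$.pid <- ok
    rows[[j]] <- d
  }
  long <- do.call(rbind, rows)
  long <- long[order(long$.pid, long$.visit), ]
  long$.vfac <- factor(long$.visit)
  fml <- stats::as.formula(paste(".y ~ 0 +",
                                 paste0("c", seq_along(columns), collapse = " + ")))
  fit <- if (structure == "unstructured") {
    nlme::gls(fml, data = long,
              correlation = nlme::corSymm(form = ~ .visit | .pid),
              weights = nlme::varIdent(form = ~ 1 | .vfac),
              na.action = stats::na.omit, control = nlme::glsControl(
                maxIter = 100, msMaxIter = 100, returnObject = FALSE))
  } else {
    nlme::gls(fml, data = long,
              correlation = nlme::corCompSymm(form = ~ .visit | .pid),
              na.action = stats::na.omit)
  }
  beta <- as.numeric(stats::coef(fit))
  vc <- as.matrix(stats::vcov(fit))
  # reconstruct the J x J marginal covariance from the fit
  vs <- rep(1, J)
  if (!is.null(fit$modelStruct$varStruct)) {
    cf <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE,
                      allCoef = TRUE)
    vs[as.integer(names(cf))] <- cf
  }
  cmx <- diag(J)
  cs <- nlme::corMatrix(fit$modelStruct$corStruct)
  if (is.list(cs)) {
    full <- cs[[which.max(vapply(cs, nrow, integer(1L)))]]
    if (nrow(full) == J) cmx <- full
  } else if (nrow(cs) == J) cmx <- cs
  sdv <- fit$sigma * vs
  sigma <- outer(sdv, sdv) * cmx
  list(beta = beta, vcov = vc, sigma = sigma, n_iter = NA_integer_)
}

#' Fit the MMRM for one replicate design
#'
#' Restricted-maximum-likelihood fit of the marginal repeated-measures model
#' with unstructured within-patient covariance. Complete-visit data use a
#' fast EM-REML solver; incomplete data are handled by likelihood through
#' [nlme::gls()]. On non-convergence the model is refitted with compound
#' symmetry and flagged. Inference on the treatment-by-visit coefficients is
#' by two-sided Wald z tests.
#'
#' @param design an `mmrm_design` from [build_design()].
#' @param covariance `"unstructured"` (default) or `"compound_symmetry"`.
#' @return an `mmrm_fit` with per-visit `gamma`, `gamma_se`, `p_values`, the
#'   full coefficient vector `beta` and its `vcov_beta`, the estimated
#'   within-patient `covariance`, `converged`, and
#'   `covariance_structure_used`.
#' @export
fit_mmrm <- function(design, covariance = c("unstructured", "compound_symmetry")) {
  covariance <- match.arg(covariance)
  stopifnot(inherits(design, "mmrm_design"))
  y <- design$y; x <- design$x
  J <- ncol(y)
  if (J < 1L) stop("no post-baseline visits", call. = FALSE)
  if (length(unique(design$arm)) < 2L) stop("both arms must be present", call. = FALSE)
  complete <- !anyNA(y)

  used <- covariance
  res <- NULL
  if (complete) {
    res <- mmrm_em(y, x, structure = covariance)
    if (is.null(res) && covariance == "unstructured") {
      res <- mmrm_em(y, x, structure = "compound_symmetry")
      if (!is.null(res)) used <- "compound_symmetry"
    }
  } else {
    res <- tryCatch(mmrm_gls(y, x, design$columns, structure = covariance),
                    error = function(e) NULL)
    if (is.null(res) && covariance == "unstructured") {
      res <- tryCatch(mmrm_gls(y, x, design$columns, structure = "compound_symmetry"),
                      error = function(e) NULL)
      if (!is.null(res)) used <- "compound_symmetry"
    }
  }
  if (is.null(res)) {
    fit <- list(converged = FALSE, covariance_structure_used = NA_character_,
                gamma = NULL, gamma_se = NULL, p_values = NULL,
                beta = NULL, vcov_beta = NULL, covariance = NULL,
                visit_days = design$visit_days, columns = design$columns)
    class(fit) <- "mmrm_fit"
    return(fit)
  }
  beta <- stats::setNames(res$beta, design$columns)
  se <- stats::setNames(sqrt(pmax(diag(res$vcov), 0)), design$columns)
  gidx <- grep("^trt_visit", design$columns)
  gamma <- beta[gidx]
  gamma_se <- se[gidx]
  z <- gamma / gamma_se
  pv <- 2 * stats::pnorm(-abs(z))
  fit <- list(converged = TRUE, covariance_structure_used = used,
              gamma = gamma, gamma_se = gamma_se, p_values = pv,
              beta = beta, vcov_beta = res$vcov, covariance = res$sigma,
              n_iter = res$n_iter,
              visit_days = design$visit_days, columns = design$columns)
  class(fit) <- "mmrm_fit"
  fit
}

#' @export
print.mmrm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("MMRM fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("MMRM fit (%s covariance)\n", x$covariance_structure_used))
  tab <- data.frame(estimate = x$gamma, se = x$gamma_se, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Treatment p-value at the last scheduled visit
#'
#' @param fit an `mmrm_fit`.
#' @return the two-sided Wald p-value of the treatment-by-last-visit
#'   interaction, or `NA` (with a `reason` attribute) for a non-converged fit.
#' @export
treatment_pvalue <- function(fit) {
  stopifnot(inherits(fit, "mmrm_fit"))
  if (!fit$converged) {
    return(structure(NA_real_, reason = "non-converged fit"))
  }
  unname(fit$p_values[length(fit$p_values)])
}
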