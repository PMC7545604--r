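#' Synthetic ALS cohort generator
#'
#' Tools for generating synthetic longitudinal ALSFRS-R cohorts with the
#' statistical structure the downstream analysis assumes: a random-intercept,
#' random-slope linear decline observed with residual noise, a prognostic
#' pre-study progression rate ("preslope") recoverable from exported baseline
#' fields, and controlled baseline-covariate missingness. Two cohort flavours
#' are targeted: a large heterogeneous training cohort, as pooled from legacy
#' trial databases, and a smaller complete-case pool resembling a single
#' completed 12-month trial; both come from the same generator with different
#' sizes and missingness settings.
#'
#' @name synth
NULL

# Canonical factor levels, shared by the generator and the CSV reader.
SEX_LEVELS <- c("female", "male")
ONSET_LEVELS <- c("bulbar", "limb")
ESCORIAL_LEVELS <- c("probable", "definite")
RACE_LEVELS <- c("caucasian", "other")

#' Parameters of the synthetic cohort generator
#'
#' Defaults are calibrated to published ALS trial cohorts: baseline ALSFRS-R
#' around 38 points, mean decline of about 0.9 points per month with
#' substantial between-patient heterogeneity, and residual measurement noise
#' of about 3 points. `preslope_slope_corr` controls how strongly the
#' onset-delta-derived preslope tracks the true progression rate, i.e. how
#' much prognostic covariate adjustment can help downstream.
#'
#' @param n_patients number of patients.
#' @param baseline_mean,baseline_sd mean and SD of the latent baseline
#'   ALSFRS-R (points); the latent intercept is truncated to `[10, 48]`.
#' @param slope_mean,slope_sd mean and SD of the latent decline slope in
#'   points per month (negative = decline).
#' @param residual_sd SD of visit-level measurement noise (points); noise at
#'   day 0 is always zero so the exported baseline is exact.
#' @param preslope_slope_corr target correlation (magnitude, in `[0, 1]`)
#'   between the preslope computable from exported fields and the hidden
#'   latent rate.
#' @param covariate_effects named numeric vector of slope shifts (points per
#'   month). Supported names: `site_of_onset` (applied to bulbar onset),
#'   `riluzole_use` (applied when on riluzole), `vital_capacity` and `age`
#'   (applied per SD above the population mean).
#' @param missing_rates named numeric vector of per-column missingness
#'   fractions used by [inject_baseline_missingness()].
#' @param missing_mechanism `"MCAR"` or `"MAR"`.
#' @param dropout_hazard per-visit monotone dropout hazard (default 0 = off);
#'   when positive, the hazard increases with accumulated functional decline
#'   and dropout is permanent.
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   cohorts.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_patients = 509,
                             baseline_mean = 38,
                             baseline_sd = 5,
                             slope_mean = -0.9,
                             slope_sd = 0.45,
                             residual_sd = 3.0,
                             preslope_slope_corr = 0.6,
                             covariate_effects = c(site_of_onset = -0.12,
                                                   vital_capacity = 0.06),
                             missing_rates = default_missing_rates(),
                             missing_mechanism = c("MCAR", "MAR"),
                             dropout_hazard = 0,
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stop_if_not_scalar_number(n_patients, "n_patients")
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  for (nm in c("baseline_sd", "slope_sd", "residual_sd", "dropout_hazard")) {
    v <- get(nm)
    stop_if_not_scalar_number(v, nm)
    if (v < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  stop_if_not_scalar_number(preslope_slope_corr, "preslope_slope_corr")
  if (abs(preslope_slope_corr) > 1) {
    stop("preslope_slope_corr must be in [-1, 1]", call. = FALSE)
  }
  if (length(missing_rates) && (any(missing_rates < 0) || any(missing_rates > 1))) {
    stop("missing_rates must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 residual_sd = residual_sd,
                 preslope_slope_corr = abs(preslope_slope_corr),
                 covariate_effects = covariate_effects,
                 missing_rates = missing_rates,
                 missing_mechanism = missing_mechanism,
                 dropout_hazard = dropout_hazard,
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Default per-column baseline missingness fractions
#'
#' BMI and height carry the heaviest missingness (over 40%); all other
#' demographic columns stay below 25%. Outcome-side columns (baseline
#' ALSFRS-R and subscores) are never masked.
#'
#' @return named numeric vector of fractions.
#' @export
default_missing_rates <- function() {
  c(bmi = 0.42, height = 0.42, weight = 0.20, vital_capacity = 0.12,
    el_escorial = 0.10, diag_delta_days = 0.18, race = 0.08,
    riluzole_use = 0.05, site_of_onset = 0.02, onset_delta_days = 0.05)
}

empty_baseline <- function() {
  data.frame(patient_id = character(), age = double(),
             sex = factor(character(), levels = SEX_LEVELS),
             site_of_onset = factor(character(), levels = ONSET_LEVELS),
             el_escorial = factor(character(), levels = ESCORIAL_LEVELS),
             riluzole_use = logical(),
             onset_delta_days = double(), diag_delta_days = double(),
             bmi = double(), height = double(), weight = double(),
             race = factor(character(), levels = RACE_LEVELS),
             vital_capacity = double(),
             baseline_frs = integer(), sub_bulbar = integer(),
             sub_fine_motor = integer(), sub_gross_motor = integer(),
             sub_respiratory = integer(),
             stringsAsFactors = FALSE)
}

# Allocate an ALSFRS-R total into four subscores, each in [0, 12].
allocate_subscores <- function(totals) {
  k <- 4L
  out <- matrix(0L, nrow = length(totals), ncol = k)
  for (i in seq_along(totals)) {
    draw <- as.integer(stats::rmultinom(1L, totals[i], prob = rep(1 / k, k)))
    # redistribute any overflow above the per-domain cap of 12
    while (any(draw > 12L)) {
      j <- which.max(draw)
      cap <- which(draw < 12L)
      recv <- cap[sample.int(length(cap), 1L)]
      draw[j] <- draw[j] - 1L
      draw[recv] <- draw[recv] + 1L
    }
    out[i, ] <- draw
  }
  out
}

#' Generate a synthetic longitudinal ALS cohort
#'
#' Patient trajectories follow `Y_ij = round(clamp(b0_i + s_i * t_ij + e_ij,
#' 0, 48))` with a truncated-normal latent baseline `b0_i`, a normal latent
#' slope `s_i` (points/month, shifted by covariate effects), and normal
#' residual noise zeroed at day 0 so the exported baseline is exact. The time
#' from symptom onset to baseline is constructed as
#' `(48 - baseline score) / rate` with `rate` a noisy copy of the latent
#' decline rate, so the preslope formula recovers the latent rate at the
#' requested correlation.
#'
#' @param params a [generator_params()] object.
#' @param schedule_days sorted non-negative integer visit days starting at 0.
#' @return a `longitudinal_dataset`: list with elements `baseline` (one row
#'   per patient), `visits` (long table `patient_id, day, alsfrs_r`),
#'   `latent` (hidden truth, never exported by [write_cohort()]), and
#'   `schedule_days`.
#' @export
generate_cohort <- function(params = generator_params(), schedule_days) {
  stopifnot(inherits(params, "generator_params"))
  if (length(schedule_days) == 0L) stop("schedule_days must be non-empty", call. = FALSE)
  if (is.unsorted(schedule_days, strictly = TRUE)) {
    stop("schedule_days must be strictly increasing", call. = FALSE)
  }
  if (schedule_days[1L] != 0) stop("schedule_days must start at 0", call. = FALSE)
  n <- params$n_patients
  if (n == 0L) {
    ds <- list(baseline = empty_baseline(),
               visits = data.frame(patient_id = character(), day = double(),
                                   alsfrs_r = integer(), stringsAsFactors = FALSE),
               latent = data.frame(patient_id = character(), latent_rate = double()),
               schedule_days = schedule_days, params = params)
    class(ds) <- "longitudinal_dataset"
    return(ds)
  }

  run_seeded(params$seed, {
    pid <- sprintf("P%05d", seq_len(n))
    age <- pmin(pmax(stats::rnorm(n, 56, 11), 18), 90)
    sex <- factor(ifelse(stats::runif(n) < 0.63, "male", "female"), levels = SEX_LEVELS)
    site <- factor(ifelse(stats::runif(n) < 0.25, "bulbar", "limb"), levels = ONSET_LEVELS)
    esc <- factor(ifelse(stats::runif(n) < 0.45, "definite", "probable"),
                  levels = ESCORIAL_LEVELS)
    ril <- stats::runif(n) < 0.70
    race <- factor(ifelse(stats::runif(n) < 0.93, "caucasian", "other"),
                   levels = RACE_LEVELS)
    height <- stats::rnorm(n, 170, 10)
    bmi <- pmin(pmax(stats::rnorm(n, 25.5, 4), 15), 45)
    weight <- bmi * (height / 100)^2
    vc <- pmin(pmax(stats::rnorm(n, 90, 15), 40), 140)

    # latent baseline, truncated to [10, 48] by rejection
    b0 <- stats::rnorm(n, params$baseline_mean, params$baseline_sd)
    bad <- which(b0 < 10 | b0 > 48)
    while (length(bad)) {
      b0[bad] <- stats::rnorm(length(bad), params$baseline_mean, params$baseline_sd)
      bad <- bad[b0[bad] < 10 | b0[bad] > 48]
    }

    # latent slope in points/month with covariate shifts
    eff <- function(nm) {
      e <- params$covariate_effects
      if (!is.null(e) && nm %in% names(e)) e[[nm]] else 0
    }
    shift <- eff("site_of_onset") * (site == "bulbar") +
      eff("riluzole_use") * ril +
      eff("vital_capacity") * (vc - 90) / 15 +
      eff("age") * (age - 56) / 11
    slope <- params$slope_mean + shift + stats::rnorm(n, 0, params$slope_sd)

    baseline_frs <- as.integer(round(pmin(pmax(b0, 0), 48)))
    subs <- allocate_subscores(baseline_frs)

    # preslope construction: noisy copy of the decline magnitude
    m <- pmax(-slope, 0.07)                     # points/month, floored
    rho <- params$preslope_slope_corr
    if (rho >= 1) {
      pre_rate <- m
    } else if (rho <= 0) {
      pre_rate <- pmax(stats::rnorm(n, mean(m), max(stats::sd(m), 1e-6)), 0.05)
    } else {
      sd_m <- if (n > 1) max(stats::sd(m), 1e-6) else params$slope_sd
      eta_sd <- sd_m * sqrt(1 / rho^2 - 1)
      pre_rate <- pmax(m + stats::rnorm(n, 0, eta_sd), 0.05)
    }
    deficit <- pmax(48 - baseline_frs, 0.5)
    onset_delta <- deficit / (pre_rate / DAYS_PER_MONTH)   # days, always > 0
    diag_delta <- onset_delta * stats::runif(n, 0.3, 0.8)

    baseline <- data.frame(patient_id = pid, age = age, sex = sex,
                           site_of_onset = site, el_escorial = esc,
                           riluzole_use = ril,
                           onset_delta_days = onset_delta,
                           diag_delta_days = diag_delta,
                           bmi = bmi, height = height, weight = weight,
                           race = race, vital_capacity = vc,
                           baseline_frs = baseline_frs,
                           sub_bulbar = subs[, 1L], sub_fine_motor = subs[, 2L],
                           sub_gross_motor = subs[, 3L],
                           sub_respiratory = subs[, 4L],
                           stringsAsFactors = FALSE)

    slope_day <- slope / DAYS_PER_MONTH
    J <- length(schedule_days)
    eps <- matrix(stats::rnorm(n * J, 0, params$residual_sd), nrow = n)
    eps[, 1L] <- 0
    yl <- outer(b0, rep(1, J)) + outer(slope_day, schedule_days) + eps
    y <- matrix(as.integer(round(pmin(pmax(yl, 0), 48))), nrow = n)

    visits <- data.frame(patient_id = rep(pid, each = J),
                         day = rep(as.double(schedule_days), times = n),
                         alsfrs_r = as.integer(t(y)),
                         stringsAsFactors = FALSE)

    if (params$dropout_hazard > 0 && J > 1L) {
      keep <- matrix(TRUE, nrow = n, ncol = J)
      for (j in 2:J) {
        decline <- pmax(y[, 1L] - y[, j - 1L], 0)
        h <- stats::plogis(stats::qlogis(params$dropout_hazard) + 0.08 * decline)
        drop_now <- keep[, j - 1L] & (stats::runif(n) < h)
        keep[, j] <- keep[, j - 1L] & !drop_now
      }
      visits <- visits[as.logical(t(keep)), , drop = FALSE]
      rownames(visits) <- NULL
    }

    latent <- data.frame(patient_id = pid, latent_rate = slope_day,
                         stringsAsFactors = FALSE)
    ds <- list(baseline = baseline, visits = visits, latent = latent,
               schedule_days = as.double(schedule_days), params = params)
    class(ds) <- "longitudinal_dataset"
    ds
  })
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat(sprintf("Synthetic longitudinal ALS cohort: %d patients, %d visit rows\n",
              nrow(x$baseline), nrow(x$visits)))
  cat("Visit schedule (days):", paste(x$schedule_days, collapse = ", "), "\n")
  invisible(x)
}

#' Mask baseline covariates missing-completely- or missing-at-random
#'
#' Under MCAR every cell of a listed column is masked independently at the
#' column rate. Under MAR the masking probability is a logistic function of
#' the patient's observed age and baseline ALSFRS-R (never of the masked value
#' itself), with the intercept solved so the marginal rate matches the
#' requested column rate; `age` itself is masked MCAR under MAR to avoid
#' self-dependence, and `baseline_frs` is never masked.
#'
#' @param table baseline covariate data.frame (one row per patient) containing
#'   at least `age` and `baseline_frs`.
#' @param rates named fractions per column; defaults from the params.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed integer seed.
#' @return the table with `NA`s injected.
#' @export
inject_baseline_missingness <- function(table,
                                        rates = default_missing_rates(),
                                        mechanism = c("MCAR", "MAR"),
                                        seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.data.frame(table))
  if (length(rates) && (any(rates < 0) || any(rates > 1))) {
    stop("missingness rates must be in [0, 1]", call. = FALSE)
  }
  rates <- rates[names(rates) %in% names(table)]
  rates <- rates[rates > 0]
  if (!length(rates) || nrow(table) == 0L) return(table)

  run_seeded(seed, {
    n <- nrow(table)
    if (mechanism == "MAR") {
      z_age <- as.numeric(scale(table$age))
      z_frs <- as.numeric(scale(table$baseline_frs))
      if (anyNA(z_age) || anyNA(z_frs)) {
        z_age[is.na(z_age)] <- 0
        z_frs[is.na(z_frs)] <- 0
      }
      lin <- 1.0 * z_age - 1.0 * z_frs
    }
    for (nm in names(rates)) {
      r <- rates[[nm]]
      if (mechanism == "MCAR" || nm %in% c("age", "baseline_frs")) {
        mask <- stats::runif(n) < r
      } else {
        a <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - r,
                            lower = -30, upper = 30)$root
        mask <- stats::runif(n) < stats::plogis(a + lin)
      }
      table[[nm]][mask] <- NA
    }
    table
  })
}

#' Write a cohort to plain-text CSV files
#'
#' Writes `visits.csv` (`patient_id, day, alsfrs_r`) and `baseline.csv` (one
#' row per patient; empty string encodes a missing value). Doubles are
#' serialized with 17 significant digits so the round-trip through
#' [read_cohort()] is lossless. The hidden latent rate is never exported.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pv <- file.path(dir, "visits.csv")
  pb <- file.path(dir, "baseline.csv")
  utils::write.table(format_lossless(dataset$visits), pv, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(format_lossless(dataset$baseline), pb, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(c(visits = pv, baseline = pb))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `visits.csv` and `baseline.csv`.
#' @return a `longitudinal_dataset` (without latent truth).
#' @export
read_cohort <- function(dir) {
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            colClasses = c(patient_id = "character",
                                           day = "numeric", alsfrs_r = "integer"),
                            na.strings = "")
  bl <- utils::read.csv(file.path(dir, "baseline.csv"),
                        colClasses = "character", na.strings = "")
  template <- empty_baseline()
  for (nm in names(template)) {
    if (!nm %in% names(bl)) next
    tcol <- template[[nm]]
    if (is.factor(tcol)) {
      bl[[nm]] <- factor(bl[[nm]], levels = levels(tcol))
    } else if (is.logical(tcol)) {
      bl[[nm]] <- as.logical(bl[[nm]])
    } else if (is.integer(tcol)) {
      bl[[nm]] <- as.integer(bl[[nm]])
    } else if (is.double(tcol)) {
      bl[[nm]] <- as.double(bl[[nm]])
    }
  }
  ds <- list(baseline = bl, visits = visits, latent = NULL,
             schedule_days = sort(unique(visits$day)), params = NULL)
  class(ds) <- "longitudinal_dataset"
  ds
}
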