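#' Configuration-driven pipeline
#'
#' Ties the stages together: generate synthetic cohorts, impute baseline
#' missingness, train the three predictors, validate them on a held-out
#' trial-like pool, simulate trials over a grid of sample sizes and effects,
#' and report power, win-rate, and effective-sample-size tables. Every run
#' writes a JSON manifest (config, seed, package version) so outputs can be
#' reproduced bit-identically.
#'
#' @name iface
NULL

run_config_defaults <- function() {
  list(
    training = list(n_patients = 3160, visit_months = c(0, 3, 6, 9, 12),
                    inject_missingness = TRUE, mechanism = "MAR"),
    pool = list(n_patients = 509),
    generator = list(baseline_mean = 38, baseline_sd = 5, slope_mean = -0.9,
                     slope_sd = 0.45, residual_sd = 3.0,
                     preslope_slope_corr = 0.6),
    predictors = list(rf_trees = 500, rf_mtry = 8, sl_folds = 10),
    schedules = c(12),
    n_grid = c(120, 200, 280, 360),
    e_grid = c(0, 0.25, 0.4),
    n_replicates = 2000,
    alpha = 0.05,
    specs = ANALYSIS_SPEC_NAMES,
    output_dir = "alspower-output",
    master_seed = 20200830)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and rejects unknown
#' keys.
#'
#' @param path YAML file path, or `NULL`.
#' @param overrides named list overriding file values (highest precedence).
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  merge_into <- function(base, new, where) {
    unknown <- setdiff(names(new), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s) %s in %s",
                   paste(sQuote(unknown), collapse = ", "), where), call. = FALSE)
    }
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        merge_into(base[[nm]], new[[nm]], paste0(where, "$", nm))
      } else new[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, user, "config")
  cfg <- merge_into(cfg, overrides, "overrides")
  # YAML sequences mixing integers and reals arrive as lists; flatten them
  for (nm in c("schedules", "n_grid", "e_grid")) {
    if (is.list(cfg[[nm]])) cfg[[nm]] <- as.numeric(unlist(cfg[[nm]]))
  }
  stopifnot(all(cfg$specs %in% ANALYSIS_SPEC_NAMES),
            all(cfg$schedules %in% c(6, 12, 18)),
            all(cfg$e_grid >= 0 & cfg$e_grid < 1),
            all(cfg$n_grid %% 2 == 0))
  class(cfg) <- "run_config"
  cfg
}

training_schedule_days <- function(cfg) {
  unique(round(sort(cfg$training$visit_months) * DAYS_PER_MONTH))
}

pool_schedule_days <- function(cfg) {
  days <- unlist(lapply(cfg$schedules, function(d) visit_schedule(d)$days))
  sort(unique(days))
}

#' Run the full pipeline from a configuration
#'
#' Stages: `generate` (training cohort and trial pool CSVs), `impute`
#' (Little's MCAR test and missForest-style completion of the training
#' baseline), `train` (RF, LME, super learner), `validate` (MSPE and
#' observed-on-predicted diagnostics on the pool, total scale, change scale,
#' and by month), `simulate` (replicate p-values over the n/E/duration grid),
#' `report` (power, win-rate, and effective-sample-size tables). All outputs
#' are plain-text CSV/JSON under `config$output_dir`.
#'
#' @param config a `run_config` from [read_run_config()].
#' @param stages subset of stages to run (later stages recompute what they
#'   need in memory).
#' @param verbose print progress.
#' @return invisibly, a list with the in-memory artifacts (cohorts, models,
#'   validation tables, p-value tables, summary tables).
#' @export
run_pipeline <- function(config = read_run_config(),
                         stages = c("generate", "impute", "train", "validate",
                                    "simulate", "report"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$master_seed
  art <- list(config = config)

  gp <- function(n, seed_off, extra = list()) {
    do.call(generator_params, c(list(n_patients = n,
                                     seed = child_seed(seed, seed_off)),
                                config$generator, extra))
  }

  say("generate: training cohort (n = %d) and trial pool (n = %d)",
      config$training$n_patients, config$pool$n_patients)
  train_ds <- generate_cohort(gp(config$training$n_patients, 1L),
                              training_schedule_days(config))
  pool <- generate_cohort(gp(config$pool$n_patients, 2L), pool_schedule_days(config))
  if (isTRUE(config$training$inject_missingness)) {
    train_ds$baseline <- inject_baseline_missingness(
      train_ds$baseline, mechanism = config$training$mechanism,
      seed = child_seed(seed, 3L))
  }
  if ("generate" %in% stages) {
    write_cohort(train_ds, file.path(out_dir, "training"))
    write_cohort(pool, file.path(out_dir, "pool"))
  }
  art$training <- train_ds; art$pool <- pool

  if (any(c("impute", "train", "validate", "simulate", "report") %in% stages)) {
    if (anyNA(train_ds$baseline)) {
      say("impute: Little's MCAR test + missForest-style completion")
      art$mcar_test <- little_mcar_test(train_ds$baseline)
      imp <- missforest_impute(train_ds$baseline, seed = child_seed(seed, 4L))
      art$imputation <- imp
      train_ds$baseline <- imp$completed
      art$training <- train_ds
      if ("impute" %in% stages) {
        utils::write.csv(format_lossless(train_ds$baseline),
                         file.path(out_dir, "training_baseline_imputed.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          list(d2 = art$mcar_test$d2, df = art$mcar_test$df,
               p_value = art$mcar_test$p_value,
               n_patterns = art$mcar_test$n_patterns),
          file.path(out_dir, "mcar_test.json"), auto_unbox = TRUE, digits = NA)
      }
    }
  }

  models <- NULL
  if (any(c("train", "validate", "simulate", "report") %in% stages)) {
    say("train: RF (%d trees), LME, super learner (%d folds)",
        config$predictors$rf_trees, config$predictors$sl_folds)
    ft <- build_feature_table(train_ds)
    rf <- fit_rf(ft$features, ft$outcome,
                 rf_config(n_trees = config$predictors$rf_trees,
                           mtry = config$predictors$rf_mtry,
                           seed = child_seed(seed, 5L)))
    lme <- fit_lme_predictor(train_ds)
    sl <- fit_superlearner(ft$features, ft$outcome,
                           k_folds = config$predictors$sl_folds,
                           seed = child_seed(seed, 6L), group = ft$patient_id)
    models <- list(rf = rf, lme = lme, sl = sl)
    art$models <- models
  }

  if ("validate" %in% stages) {
    say("validate: external metrics on the trial pool")
    post_days <- pool$schedule_days[pool$schedule_days > 0]
    val <- list()
    for (nm in names(models)) {
      pm <- predict_grid(models[[nm]], pool$baseline, post_days)
      preds <- data.frame(patient_id = rep(rownames(pm), times = ncol(pm)),
                          day = rep(post_days, each = nrow(pm)),
                          pred = as.numeric(pm))
      val[[nm]] <- list(total = total_metrics(pool, preds),
                        change = change_metrics(pool, preds),
                        by_month = metrics_by_month(pool, preds))
    }
    art$validation <- val
    tab <- do.call(rbind, lapply(names(val), function(nm) {
      cbind(data.frame(model = nm, scale = c("total", "change")),
            rbind(as.data.frame(val[[nm]]$total), as.data.frame(val[[nm]]$change)))
    }))
    utils::write.csv(tab, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }

  if (any(c("simulate", "report") %in% stages)) {
    say("simulate: %d replicates per scenario", config$n_replicates)
    results <- list()
    scen <- 0L
    for (dur in config$schedules) for (e in config$e_grid) for (n in config$n_grid) {
      scen <- scen + 1L
      cfgt <- trial_config(duration_months = dur, n_total = n, effect_e = e,
                           n_replicates = config$n_replicates,
                           master_seed = child_seed(seed, 100L + scen))
      results[[sprintf("d%02d_e%03.0f_n%03d", dur, 100 * e, n)]] <-
        run_replicates(pool, cfgt, specs = lapply(config$specs, analysis_spec),
                       models = models)
    }
    art$results <- results
    if ("simulate" %in% stages) {
      for (nm in names(results)) {
        utils::write.csv(as.data.frame(results[[nm]]$p_values),
                         file.path(out_dir, paste0("pvalues_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }

  if ("report" %in% stages) {
    say("report: power, win rates, effective sample size")
    summ <- power_summary(art$results, alpha = config$alpha)
    utils::write.csv(summ, file.path(out_dir, "power_summary.csv"), row.names = FALSE)
    wr <- do.call(rbind, lapply(names(art$results), function(nm) {
      w <- win_rates(art$results[[nm]]$p_values)
      data.frame(scenario = nm, spec = names(w$rates), win_rate = w$rates,
                 row.names = NULL)
    }))
    utils::write.csv(wr, file.path(out_dir, "win_rates.csv"), row.names = FALSE)
    art$power <- summ; art$win_rates <- wr
  }

  manifest <- list(package_version = as.character(utils::packageVersion("alspower")),
                   r_version = as.character(getRversion()),
                   master_seed = seed,
                   config = unclass(config),
                   stages = stages,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(art)
}

#' Plot power curves by scenario
#'
#' One panel per (duration, effect) with power against total enrollment, one
#' line per analysis model. Requires `ggplot2`.
#'
#' @param summary a `power_summary` data.frame.
#' @return a ggplot object.
#' @export
plot_power_curves <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$n_total, y = .data$power,
                               colour = .data$spec)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(duration_months ~ effect_e,
                        labeller = ggplot2::label_both) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 3) +
    ggplot2::labs(x = "total enrollment", y = "power") +
    ggplot2::theme_bw()
}
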