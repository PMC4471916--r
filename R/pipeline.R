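#' Per-male song feature table
#'
#' Computes the nine song measures per male: repertoire size, the three
#' category repertoire sizes, the three category occurrences, and the two
#' network orderliness metrics.
#'
#' @param sequences named list of \code{\link{song_sequence}} objects.
#' @param window repertoire window (default 533 songs).
#' @param drop_self_loops passed to \code{\link{build_network}}.
#' @return Data frame, one row per male.
#' @export
song_features <- function(sequences, window = 533L, drop_self_loops = TRUE) {
  rows <- lapply(sequences, function(s) {
    rep <- compute_repertoire(s, window = window)
    met <- network_metrics(s, drop_self_loops = drop_self_loops)
    rep$average_shortest_path <- met$average_shortest_path
    rep$transitivity <- met$transitivity
    rep
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

SONG_MEASURES <- c("repertoire_size", "whistle_repertoire", "whistle_occurrence",
                   "trill_repertoire", "trill_occurrence", "buzz_repertoire",
                   "buzz_occurrence", "average_shortest_path", "transitivity")

#' Pipeline run configuration
#'
#' Either \code{sim} (a \code{\link{sim_config}}) for a synthetic study, or
#' the three input paths for field-format data. All stage parameters have
#' the conventional defaults. One master \code{seed} governs every
#' stochastic stage through a documented derivation (stage offsets), so
#' stages stay independently reproducible.
#'
#' @param sim optional \code{\link{sim_config}}.
#' @param sequences_path,rfid_path,metadata_path input files (used when
#'   \code{sim} is NULL).
#' @param window repertoire window (533).
#' @param min_gap visit-merge threshold, seconds (60).
#' @param morning_end,evening_start session boundaries.
#' @param nfolds,rule LASSO cross-validation settings.
#' @param kernel,C,gamma,epsilon SVR hyperparameters.
#' @param reselect re-run selection inside each LOO round.
#' @param seed master seed.
#' @return List of class \code{run_config}.
#' @export
pipeline_config <- function(sim = NULL, sequences_path = NULL,
                            rfid_path = NULL, metadata_path = NULL,
                            window = 533L, min_gap = 60,
                            morning_end = "10:00", evening_start = "18:00",
                            nfolds = 5L, rule = "1se",
                            kernel = "rbf", C = 1, gamma = NULL, epsilon = 0.1,
                            reselect = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  have_files <- !is.null(sequences_path) && !is.null(rfid_path) &&
    !is.null(metadata_path)
  if (is.null(sim) && !have_files) {
    stop_input("pipeline_config needs either a simulation block or all three input paths")
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain data (simulate or read); (2) song features per male;
#' (3) RFID events to visits, session rates, per-male medians and the
#' between-male ANOVA; (4) assemble the feature table (9 song measures +
#' hatchlings + year) with the median feeding rate as response; (5) LASSO
#' feature selection; (6) leave-one-out SVR prediction using the selected
#' song measures plus number of hatchlings; (7) Spearman evaluation of
#' predicted vs observed rates. Deterministic given config + seed; stages
#' are logged to stderr with timings.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress stage logging.
#' @return List of class \code{study_report}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    if (!quiet) {
      message(sprintf("[%s] done in %.2fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    out
  }

  dat <- log_stage("data", {
    if (!is.null(config$sim)) {
      study <- simulate_study(config$sim, seed = derive_seed(config$seed, "sim"))
      list(sequences = study$sequences, events = study$events,
           metadata = study$metadata, truth = study$truth)
    } else {
      list(sequences = read_sequences(config$sequences_path),
           events = read_rfid_log(config$rfid_path),
           metadata = read_delim_checked(config$metadata_path,
                                         c("male_id", "n_hatchlings", "year"),
                                         "metadata file"),
           truth = NULL)
    }
  })
  if (length(dat$sequences) < 3L) {
    stop_input("pipeline requires at least 3 males")
  }

  feats <- log_stage("song_features", song_features(dat$sequences, window = config$window))

  feeding <- log_stage("feeding", {
    visits <- events_to_visits(dat$events, min_gap = config$min_gap)
    rates <- session_rates(visits, morning_end = config$morning_end,
                           evening_start = config$evening_start)
    list(visits = visits, rates = rates,
         summary = summarize_feeding(rates),
         anova = feeding_anova(rates))
  })

  table_fit <- log_stage("feature_table", {
    md <- dat$metadata
    md$male_id <- as.character(md$male_id)
    tab <- merge(feats, md, by = "male_id", sort = TRUE)
    tab <- merge(tab, feeding$summary[, c("male_id", "median_rate")],
                 by = "male_id", sort = TRUE)
    if (anyNA(tab)) stop_input("feature table contains missing values")
    tab$year <- factor(tab$year)
    tab
  })

  selection <- log_stage("lasso", {
    std <- standardize_features(
      table_fit[, c(SONG_MEASURES, "n_hatchlings", "year"), drop = FALSE])
    set.seed(derive_seed(config$seed, "cv"))
    suppressWarnings(select_features(std$x, table_fit$median_rate,
                                     rule = config$rule, nfolds = config$nfolds))
  })

  loo <- log_stage("loo_svr", {
    selected_song <- intersect(selection$selected, SONG_MEASURES)
    predictors <- union(selected_song, "n_hatchlings")
    set.seed(derive_seed(config$seed, "loo"))
    loo_predict(table_fit, table_fit$median_rate, predictors = predictors,
                male_id = table_fit$male_id, reselect = config$reselect,
                kernel = config$kernel, C = config$C, gamma = config$gamma,
                epsilon = config$epsilon, nfolds = config$nfolds,
                rule = config$rule)
  })

  evaluation <- log_stage("evaluate", spearman_eval(loo$predicted, loo$observed))

  table1 <- format_measure_table(describe_measures(feats[, SONG_MEASURES]))

  structure(list(
    measure_stats = table1,
    features = table_fit,
    session_rates = feeding$rates,
    feeding_summary = feeding$summary,
    anova = feeding$anova,
    lasso = list(selected = selection$selected,
                 coefficients = as.list(selection$coefficients),
                 lambda = selection$lambda, rule = selection$rule),
    loo = as.data.frame(loo),
    evaluation = list(rho = evaluation$rho, p_value = evaluation$p_value,
                      n = evaluation$n),
    truth = dat$truth,
    provenance = list(package = "nightsong",
                      version = as.character(utils::packageVersion("nightsong")),
                      seed = config$seed,
                      n_males = length(dat$sequences))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d males\n", x$provenance$n_males))
  print(x$anova)
  cat(sprintf("LASSO selected: %s\n",
              if (length(x$lasso$selected)) paste(x$lasso$selected, collapse = ", ")
              else "(none)"))
  cat(sprintf("LOO SVR: Spearman rho = %.3f, p = %.4g\n",
              x$evaluation$rho, x$evaluation$p_value))
  invisible(x)
}

report_json <- function(report) {
  keep <- report[c("measure_stats", "features", "feeding_summary", "anova",
                   "lasso", "loo", "evaluation", "provenance")]
  keep$anova <- unclass(keep$anova)
  jsonlite::toJSON(keep, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                   pretty = TRUE, na = "null", POSIXt = "ISO8601")
}

#' Write a study report to disk
#'
#' Writes \code{report.json} plus delimited tables (features, session rates,
#' feeding summary, leave-one-out predictions) under \code{dir}. Timestamps
#' are excluded from the JSON so identical runs produce identical files.
#'
#' @param report a \code{study_report}.
#' @param dir output directory.
#' @return Named vector of paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "report.json"),
             features = file.path(dir, "features.csv"),
             sessions = file.path(dir, "session_rates.csv"),
             feeding = file.path(dir, "feeding_summary.csv"),
             loo = file.path(dir, "loo_predictions.csv"))
  writeLines(report_json(report), paths["json"])
  write_delim_out(report$features, paths["features"])
  write_delim_out(report$session_rates, paths["sessions"])
  write_delim_out(report$feeding_summary, paths["feeding"])
  write_delim_out(report$loo, paths["loo"])
  paths
}

#' Diagnostic figures for a study report
#'
#' Writes two PNGs: per-male session feeding rates with the median overlaid,
#' and predicted vs actual feeding rates from the leave-one-out SVR.
#' Renders headlessly (type = "cairo" is not required; the default png
#' device is used).
#'
#' @param report a \code{study_report}.
#' @param dir output directory.
#' @return Character vector of the two file paths.
#' @export
make_figures <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "feeding_rates.png")
  f2 <- file.path(dir, "predicted_vs_actual.png")

  rates <- report$session_rates
  males <- sort(unique(rates$male_id))
  grDevices::png(f1, width = 900, height = 500)
  graphics::plot(NA, xlim = c(0.5, length(males) + 0.5),
                 ylim = range(rates$rate), xaxt = "n",
                 xlab = "male", ylab = "session feeding rate (visits/h)",
                 main = "Individual feeding rates")
  graphics::axis(1, at = seq_along(males), labels = males, las = 2, cex.axis = 0.8)
  ix <- match(rates$male_id, males)
  graphics::points(jitter(ix, amount = 0.15), rates$rate, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.6))
  med <- report$feeding_summary
  graphics::points(match(med$male_id, males), med$median_rate, pch = 3,
                   cex = 1.4, lwd = 2, col = "firebrick")
  grDevices::dev.off()

  loo <- report$loo
  grDevices::png(f2, width = 550, height = 550)
  rng <- range(c(loo$observed, loo$predicted))
  graphics::plot(loo$observed, loo$predicted, pch = 16, xlim = rng, ylim = rng,
                 xlab = "actual feeding rate (visits/h)",
                 ylab = "predicted feeding rate (visits/h)",
                 main = sprintf("LOO SVR prediction (rho = %.2f)",
                                report$evaluation$rho))
  graphics::abline(0, 1, lty = 2, col = "grey40")
  grDevices::dev.off()

  c(f1, f2)
}
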