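#' Compare observed burst-size noise with pure-heterogeneity predictions
#'
#' For each lysis time, sets the observed CV^2 of occupied-well plaque
#' counts against the first-order predictions of [cv2_burst()] under three
#' single-source hypotheses: all cell-to-cell variability in `k_max`
#' (capacity), all in `LT50`, or all in `r`. Each hypothesis has one free
#' scalar (its CV^2), calibrated by least squares of the observed profile
#' on the squared-sensitivity profile. A capacity-only budget predicts a
#' flat profile; `LT50`- or `r`-only budgets predict decay toward zero at
#' long lysis times, so the shape of the observed profile discriminates
#' the sources.
#'
#' @param wells Well-level data frame ([read_assay_csv()] format).
#' @param params [burst_params()] at which to evaluate sensitivities
#'   (typically a fit to the same data).
#' @param use_trimmed Use the outlier-trimmed CV^2 instead of the raw one.
#' @return An object of class `"noise_decomposition"`: list with
#'   `table` (per lysis time: observed CV^2, the three predictions),
#'   `calibrated_cv2` (the fitted scalar for each hypothesis) and `rss`
#'   (residual sum of squares of each hypothesis against the observations).
#' @export
decompose_noise <- function(wells, params, use_trimmed = FALSE) {
  params <- as_burst_params(params)
  summ <- summarize_assay(wells, n_boot = 0L)
  obs <- if (use_trimmed) summ$cv2_trimmed else summ$cv2
  lt <- summ$lysis_time_min
  keep <- lt > params$D & is.finite(obs)
  lt <- lt[keep]; obs <- obs[keep]
  S <- burst_sensitivities(lt, params)
  S2 <- cbind(kmax = S$S_kmax^2, LT50 = S$S_LT50^2, r = S$S_r^2)
  cal <- vapply(colnames(S2), function(nm) {
    s2 <- S2[, nm]
    sum(s2 * obs) / sum(s2^2)
  }, numeric(1))
  pred <- sweep(S2, 2, cal, `*`)
  rss <- colSums((obs - pred)^2)
  structure(list(
    table = data.frame(lysis_time_min = lt, observed_cv2 = obs,
                       pred_capacity_only = pred[, "kmax"],
                       pred_LT50_only = pred[, "LT50"],
                       pred_r_only = pred[, "r"]),
    calibrated_cv2 = cal,
    rss = rss
  ), class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat("Burst-size noise decomposition (single-source hypotheses)\n")
  cat(sprintf("  calibrated CV^2: capacity %.4f | LT50 %.4g | r %.4g\n",
              x$calibrated_cv2["kmax"], x$calibrated_cv2["LT50"],
              x$calibrated_cv2["r"]))
  cat(sprintf("  RSS:             capacity %.3g | LT50 %.3g | r %.3g\n",
              x$rss["kmax"], x$rss["LT50"], x$rss["r"]))
  print(x$table, digits = 4)
  invisible(x)
}

#' Trend of burst-size noise against mean burst size
#'
#' Ordinary least-squares slope of per-lysis-time CV^2 against mean burst
#' size, with a percentile bootstrap confidence interval obtained by
#' resampling occupied wells within each lysis time. A slope interval
#' covering zero is the flat-noise signature of capacity-dominated
#' heterogeneity; this is a descriptive summary, not a formal test.
#'
#' @param wells Well-level data frame.
#' @param n_boot Bootstrap replicates (default 500).
#' @param level Confidence level.
#' @return List with `slope`, `ci` (lo, hi), `level`, `n_boot`, and the
#'   per-timepoint `points` used for the regression.
#' @export
noise_trend <- function(wells, n_boot = 500L, level = 0.95) {
  wells <- validate_wells(wells)
  occupied <- wells[wells$plaque_count > 0, ]
  split_counts <- split(occupied$plaque_count, occupied$lysis_time_min)
  split_counts <- split_counts[vapply(split_counts, length, integer(1)) >= 2L]
  if (length(split_counts) < 3L)
    stop("need at least 3 lysis times with >= 2 occupied wells", call. = FALSE)
  stat <- function(counts_list) {
    m <- vapply(counts_list, mean, numeric(1))
    cv2 <- vapply(counts_list, function(x) (stats::sd(x) / mean(x))^2,
                  numeric(1))
    unname(stats::coef(stats::lm(cv2 ~ m))[2])
  }
  slope <- stat(split_counts)
  boots <- vapply(seq_len(n_boot), function(b) {
    stat(lapply(split_counts, function(x)
      sample(x, length(x), replace = TRUE)))
  }, numeric(1))
  alpha <- (1 - level) / 2
  boots <- sort(boots)
  ci <- c(lo = boots[max(1L, ceiling(n_boot * alpha))],
          hi = boots[max(1L, ceiling(n_boot * (1 - alpha)))])
  m <- vapply(split_counts, mean, numeric(1))
  cv2 <- vapply(split_counts, function(x) (stats::sd(x) / mean(x))^2,
                numeric(1))
  list(slope = slope, ci = ci, level = level, n_boot = n_boot,
       points = data.frame(lysis_time_min = as.numeric(names(split_counts)),
                           mean = m, cv2 = cv2))
}

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: either a CSV of well
#' records or a simulation block (exactly one of the two), trimming,
#' bootstrap settings, fit settings, an optional viability correction, an
#' optional two-group CV comparison, and the output directory.
#'
#' @param input_csv Path to a well-level CSV, or `NULL` to simulate.
#' @param simulate An [assay_config()], or `NULL` to read `input_csv`.
#' @param out_dir Output directory (created if needed).
#' @param trim Also report trimmed summaries (always computed; this flag
#'   selects which CV^2 the decomposition uses).
#' @param n_boot Bootstrap replicates for summary confidence intervals.
#' @param level Confidence level for all intervals.
#' @param fit_n_starts Multi-start count for the model fit.
#' @param fit_boot Bootstrap replicates for fit parameter intervals
#'   (0 disables).
#' @param correction Multiplicative plaque-count correction (default 1;
#'   use `1/0.81` to undo the 19% chloroform viability loss).
#' @param cv_compare Optional numeric vector of two lysis times whose
#'   occupied-well samples are compared with both CV-equality tests.
#' @param seed Seed recorded in the run log and used for all resampling.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_csv = NULL, simulate = NULL,
                            out_dir = tempfile("phageburst_run_"),
                            trim = TRUE, n_boot = 1000L, level = 0.95,
                            fit_n_starts = 10L, fit_boot = 0L,
                            correction = 1, cv_compare = NULL, seed = 1L) {
  if (is.null(input_csv) == is.null(simulate))
    stop("supply exactly one of 'input_csv' or 'simulate'", call. = FALSE)
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "assay_config"))
    if (simulate$n_plates_per_timepoint < 1L ||
        length(simulate$lysis_times) < 1L)
      stop("simulation block must specify at least one plate and lysis time",
           call. = FALSE)
  }
  structure(list(input_csv = input_csv, simulate = simulate,
                 out_dir = out_dir, trim = isTRUE(trim),
                 n_boot = as.integer(n_boot), level = level,
                 fit_n_starts = as.integer(fit_n_starts),
                 fit_boot = as.integer(fit_boot),
                 correction = correction, cv_compare = cv_compare,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full burst-size analysis pipeline
#'
#' Sequence: obtain well records (read or simulate), per-lysis-time
#' summaries (untrimmed and trimmed, with bootstrap CIs), the nonlinear
#' model fit with predicted curve, the noise decomposition against the
#' three single-source heterogeneity hypotheses with the CV^2-vs-mean
#' trend, and optionally a two-group CV-equality comparison. Every stage's
#' output is written to `config$out_dir`:
#' `summary.csv`, `fit.json`, `curve.csv`, `decomposition.csv`,
#' `noise_trend.json`, optionally `cv_tests.csv`, `wells.csv` (and
#' `truth.json`) for simulated input, and `run_log.yaml` echoing versions,
#' seed and configuration. Re-running with the same configuration and seed
#' reproduces every output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`wells`,
#'   `summary`, `fit`, `decomposition`, `trend`, `cv_tests`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  paths <- list()

  if (!is.null(config$simulate)) {
    sim <- simulate_experiment(config$simulate)
    wells <- sim$wells
    paths$wells <- file.path(config$out_dir, "wells.csv")
    write_assay_csv(wells, paths$wells)
    paths$truth <- file.path(config$out_dir, "truth.json")
    write_truth_json(sim, paths$truth)
  } else {
    wells <- read_assay_csv(config$input_csv)
  }

  summ <- summarize_assay(wells, n_boot = config$n_boot,
                          level = config$level,
                          correction = config$correction)
  paths$summary <- file.path(config$out_dir, "summary.csv")
  utils::write.csv(summ, paths$summary, row.names = FALSE, quote = FALSE)

  # fit on untrimmed means (raw data, outliers included); trimmed results
  # stay available in the summary table
  fit <- fit_burst_model(summ$lysis_time_min, summ$mean,
                         n_starts = config$fit_n_starts)
  if (config$fit_boot > 0L)
    fit <- bootstrap_fit_cis(fit, wells, n_boot = config$fit_boot,
                             level = config$level,
                             correction = config$correction)
  paths$fit <- file.path(config$out_dir, "fit.json")
  write_fit_json(fit, paths$fit)
  grid <- seq(min(summ$lysis_time_min), max(summ$lysis_time_min),
              length.out = 101)
  paths$curve <- file.path(config$out_dir, "curve.csv")
  utils::write.csv(predict_curve(fit, grid), paths$curve,
                   row.names = FALSE, quote = FALSE)

  decomp <- decompose_noise(wells, fit$params, use_trimmed = config$trim &&
                              all(is.finite(summ$cv2_trimmed)))
  paths$decomposition <- file.path(config$out_dir, "decomposition.csv")
  utils::write.csv(decomp$table, paths$decomposition,
                   row.names = FALSE, quote = FALSE)
  trend <- noise_trend(wells, n_boot = min(config$n_boot, 500L),
                       level = config$level)
  paths$trend <- file.path(config$out_dir, "noise_trend.json")
  jsonlite::write_json(
    list(slope = trend$slope, ci_lo = unname(trend$ci["lo"]),
         ci_hi = unname(trend$ci["hi"]), level = trend$level,
         n_boot = trend$n_boot,
         note = "descriptive OLS trend of CV^2 vs mean burst size"),
    paths$trend, auto_unbox = TRUE, digits = NA)

  cv_res <- NULL
  if (!is.null(config$cv_compare)) {
    tt <- config$cv_compare
    if (length(tt) != 2L)
      stop("'cv_compare' must name exactly two lysis times", call. = FALSE)
    occ <- wells[wells$plaque_count > 0, ]
    groups <- lapply(tt, function(t1)
      occ$plaque_count[occ$lysis_time_min == t1])
    asym <- cv_test_asymptotic(groups)
    mslr <- cv_test_mslr(groups)
    cv_res <- data.frame(
      method = c("asymptotic", "modified_slr"),
      statistic = c(unname(asym$statistic), unname(mslr$statistic)),
      df = c(unname(asym$parameter), unname(mslr$parameter)),
      p_value = c(asym$p.value, mslr$p.value))
    paths$cv_tests <- file.path(config$out_dir, "cv_tests.csv")
    utils::write.csv(cv_res, paths$cv_tests, row.names = FALSE, quote = FALSE)
  }

  paths$log <- file.path(config$out_dir, "run_log.yaml")
  log <- list(
    package = "phageburst",
    package_version = as.character(utils::packageVersion("phageburst")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_wells_input = nrow(wells),
    config = list(
      input_csv = config$input_csv,
      simulated = !is.null(config$simulate),
      sim_seed = if (!is.null(config$simulate)) config$simulate$seed,
      trim = config$trim, n_boot = config$n_boot, level = config$level,
      fit_n_starts = config$fit_n_starts, fit_boot = config$fit_boot,
      correction = config$correction,
      cv_compare = config$cv_compare))
  yaml::write_yaml(log, paths$log)

  invisible(list(wells = wells, summary = summ, fit = fit,
                 decomposition = decomp, trend = trend, cv_tests = cv_res,
                 paths = paths))
}
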