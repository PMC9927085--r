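#' Moment skewness (g1) with 1/n central moments
#'
#' Third standardised central moment \eqn{g_1 = m_3 / m_2^{3/2}} computed
#' with 1/n-normalised moments (the convention of the R \pkg{moments}
#' package), not the adjusted Fisher-Pearson form. A sample with zero
#' variance has no asymmetry and returns 0 by convention.
#'
#' @param x Numeric vector, length >= 2.
#' @return The moment skewness (dimensionless).
#' @export
moment_skewness <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L || any(!is.finite(x)))
    stop("skewness needs at least two finite values", call. = FALSE)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^3) / m2^1.5
}

#' Summary statistics of a single-lysis-time burst-size sample
#'
#' Sample size, mean, standard deviation (n-1 denominator), coefficient of
#' variation (sd/mean), its square, and moment skewness for the per-well
#' plaque counts of occupied wells at one lysis time.
#'
#' @param counts Nonnegative per-well plaque counts (occupied wells only),
#'   length >= 2 with positive mean.
#' @param lysis_time Optional lysis time (minutes) carried into the output.
#' @return A one-row data frame with columns `lysis_time`, `n`, `mean`,
#'   `sd`, `cv`, `cv2`, `skewness`.
#' @examples
#' summarize_bursts(c(1, 2, 3, 4, 10))
#' @export
summarize_bursts <- function(counts, lysis_time = NA_real_) {
  x <- as.numeric(counts)
  if (length(x) < 2L)
    stop("need at least two observations to summarise a burst sample",
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("plaque counts must be finite and nonnegative", call. = FALSE)
  m <- mean(x)
  if (m <= 0)
    stop("burst sample has zero mean; CV is undefined", call. = FALSE)
  s <- stats::sd(x)
  data.frame(lysis_time = lysis_time, n = length(x), mean = m, sd = s,
             cv = s / m, cv2 = (s / m)^2, skewness = moment_skewness(x))
}

#' One-pass trimming of burst-size outliers at twice the mean
#'
#' Removes observations strictly greater than twice the untrimmed sample
#' mean (multi-cell wells sit in this tail under limiting dilution), in a
#' single pass (the threshold is not recomputed after removal). Values
#' exactly at the threshold are kept.
#'
#' @param counts Nonnegative per-well plaque counts, length >= 2.
#' @return An object of class `"trim_result"`: list with `kept` (the
#'   retained counts), `n_original`, `n_removed`, `frac_removed`,
#'   `threshold`, `mean_before`, `mean_after`, `skew_before`, `skew_after`.
#' @examples
#' trim_outliers(c(10, 10, 10, 50))
#' @export
trim_outliers <- function(counts) {
  x <- as.numeric(counts)
  if (length(x) < 2L || any(!is.finite(x)) || any(x < 0))
    stop("'counts' must be >= 2 finite nonnegative values", call. = FALSE)
  m0 <- mean(x)
  thr <- 2 * m0
  keep <- x <= thr
  kept <- x[keep]
  structure(list(
    kept = kept,
    n_original = length(x),
    n_removed = sum(!keep),
    frac_removed = mean(!keep),
    threshold = thr,
    mean_before = m0,
    mean_after = mean(kept),
    skew_before = moment_skewness(x),
    skew_after = if (length(kept) >= 2L) moment_skewness(kept) else NA_real_
  ), class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf("Trimmed %d of %d wells (%.1f%%) above threshold %.1f\n",
              x$n_removed, x$n_original, 100 * x$frac_removed, x$threshold))
  cat(sprintf("  mean %.1f -> %.1f; skewness %.2f -> %.2f\n",
              x$mean_before, x$mean_after, x$skew_before, x$skew_after))
  invisible(x)
}

.boot_stat <- function(mat, statistic) {
  # mat: n_boot x n matrix of resampled counts
  n <- ncol(mat)
  mu <- rowMeans(mat)
  if (statistic == "mean") return(mu)
  v <- (rowMeans(mat^2) - mu^2) * n / (n - 1)
  v[v < 0] <- 0
  cv <- sqrt(v) / mu
  if (statistic == "cv") cv else cv^2
}

#' Percentile bootstrap confidence interval for a burst-size statistic
#'
#' Resamples the counts with replacement `n_boot` times and returns the
#' percentile interval of the chosen statistic; interval endpoints are order
#' statistics of the resampled distribution (the `ceiling(n_boot * p)`-th
#' ordered value).
#'
#' @inheritParams summarize_bursts
#' @param statistic One of `"mean"`, `"cv"`, `"cv2"`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' bootstrap_ci(rlnorm(50, 4, 0.4), "cv2", n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(counts, statistic = c("mean", "cv", "cv2"),
                         n_boot = 1000L, level = 0.95, seed = NULL) {
  statistic <- match.arg(statistic)
  x <- as.numeric(counts)
  n <- length(x)
  if (n < 2L || any(!is.finite(x)))
    stop("'counts' must be >= 2 finite values", call. = FALSE)
  if (statistic != "mean" && mean(x) <= 0)
    stop("CV statistics need a positive sample mean", call. = FALSE)
  if (n_boot < 1L) stop("'n_boot' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  mat <- matrix(x[idx], nrow = n_boot, ncol = n)
  stat <- sort(.boot_stat(mat, statistic))
  alpha <- (1 - level) / 2
  lo <- stat[max(1L, ceiling(n_boot * alpha))]
  hi <- stat[max(1L, ceiling(n_boot * (1 - alpha)))]
  c(lo = lo, hi = hi)
}

#' Read a well-level plaque-count table
#'
#' Reads the standard assay CSV with columns `plate`, `well`,
#' `lysis_time_min`, `plaque_count` and validates it, failing fast with
#' row-level diagnostics on malformed input.
#'
#' @param path CSV file path.
#' @return Data frame of well records.
#' @export
read_assay_csv <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_wells(wells)
}

#' @rdname read_assay_csv
#' @param wells A well-level data frame to validate.
#' @export
validate_wells <- function(wells) {
  required <- c("plate", "well", "lysis_time_min", "plaque_count")
  missing <- setdiff(required, names(wells))
  if (length(missing) > 0)
    stop("well table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(wells$plaque_count) | wells$plaque_count < 0 |
                 wells$plaque_count != round(wells$plaque_count))
  if (length(bad) > 0)
    stop("invalid plaque_count (negative, missing or non-integer) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  bad_lt <- which(!is.finite(wells$lysis_time_min) | wells$lysis_time_min <= 0)
  if (length(bad_lt) > 0)
    stop("invalid lysis_time_min at row(s): ",
         paste(utils::head(bad_lt, 10), collapse = ", "),
         if (length(bad_lt) > 10) " ..." else "", call. = FALSE)
  wells
}

#' Write the analysis-facing well-level CSV
#'
#' Drops any latent simulation columns (such as the true cell count) so
#' that generated data expose exactly the columns a real assay would.
#'
#' @param wells Well-level data frame.
#' @param path Output CSV path.
#' @export
write_assay_csv <- function(wells, path) {
  keep <- c("plate", "well", "lysis_time_min", "plaque_count")
  utils::write.csv(wells[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-lysis-time summary of a limiting-dilution assay
#'
#' Splits the well table by lysis time, treats wells with zero plaques as
#' empty (a well that received no cell is indistinguishable from one whose
#' cell produced nothing), and reports untrimmed and trimmed summary
#' statistics plus a percentile bootstrap confidence interval for the
#' chosen statistic of the untrimmed sample.
#'
#' @param wells Well-level data frame (see [read_assay_csv()]).
#' @param n_boot Bootstrap replicates for the confidence interval; 0 skips
#'   the interval.
#' @param level Confidence level.
#' @param ci_statistic Statistic for the bootstrap interval (`"mean"`,
#'   `"cv"` or `"cv2"`).
#' @param correction Multiplicative correction applied to plaque counts
#'   before summarising (e.g. `1 / 0.81` to undo a known 19% viability
#'   loss). Default 1 (off); CV, CV^2 and skewness are scale-free and
#'   unaffected.
#' @return Data frame with one row per lysis time: `lysis_time_min`, `n`,
#'   `mean`, `sd`, `cv`, `cv2`, `skewness`, `ci_lo`, `ci_hi`, plus
#'   `n_trimmed`, `frac_removed`, `mean_trimmed`, `cv_trimmed`,
#'   `cv2_trimmed`, `skewness_trimmed`.
#' @export
summarize_assay <- function(wells, n_boot = 1000L, level = 0.95,
                            ci_statistic = "mean", correction = 1) {
  wells <- validate_wells(wells)
  if (!is.numeric(correction) || length(correction) != 1L || correction <= 0)
    stop("'correction' must be a positive scalar", call. = FALSE)
  occupied <- wells[wells$plaque_count > 0, ]
  if (nrow(occupied) == 0)
    stop("no occupied wells (all plaque counts are zero)", call. = FALSE)
  times <- sort(unique(occupied$lysis_time_min))
  rows <- lapply(times, function(tt) {
    x <- occupied$plaque_count[occupied$lysis_time_min == tt] * correction
    if (length(x) < 2L) return(NULL)
    s <- summarize_bursts(x, lysis_time = tt)
    tr <- trim_outliers(x)
    ts <- if (length(tr$kept) >= 2L) summarize_bursts(tr$kept) else
      data.frame(mean = NA_real_, cv = NA_real_, cv2 = NA_real_,
                 skewness = NA_real_)
    ci <- if (n_boot >= 1L)
      bootstrap_ci(x, ci_statistic, n_boot = n_boot, level = level)
    else c(lo = NA_real_, hi = NA_real_)
    data.frame(lysis_time_min = tt, n = s$n, mean = s$mean, sd = s$sd,
               cv = s$cv, cv2 = s$cv2, skewness = s$skewness,
               ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
               n_trimmed = length(tr$kept), frac_removed = tr$frac_removed,
               mean_trimmed = ts$mean, cv_trimmed = ts$cv,
               cv2_trimmed = ts$cv2, skewness_trimmed = ts$skewness)
  })
  do.call(rbind, rows)
}
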