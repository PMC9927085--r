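#' Fit the burst-size model to per-lysis-time mean burst sizes
#'
#' Nonlinear least squares for the four-parameter saturating burst-size
#' model (see [burst_params()]), using Levenberg-Marquardt
#' (\pkg{minpack.lm}) on a reparameterised scale: `log(k_max)`, `log(r)`
#' and `log(LT50 - D)` keep the optimizer inside the valid parameter
#' domain (`k_max > 0`, `r > 0`, `LT50 > D`), and `D` is box-bounded to
#' `[0, max(lysis_time))`. Because the `LT <= D` zero clause makes the
#' objective non-smooth in `D`, the fit is repeated from a fixed design of
#' perturbed starting points (deterministic multi-start) and the best
#' solution by residual sum of squares is returned.
#'
#' Automatic initialisation: `k_max` from the largest observed mean; `LT50`
#' by linear interpolation to the half-maximum crossing; `D` as the
#' smallest lysis time with a positive mean minus one sampling interval
#' (floored at 0); `r` as the slope of `log(mean)` against lysis time over
#' the rising phase.
#'
#' @param lysis_time Lysis times in minutes (>= 5 distinct values spanning
#'   the rise and the plateau).
#' @param mean_burst Observed mean burst sizes (PFU/cell), same length.
#' @param init Optional [burst_params()] starting values; default automatic.
#' @param n_starts Number of multi-start fits (default 10).
#' @param weights Optional nonnegative least-squares weights (default
#'   unweighted; supply inverse variances for a weighted fit).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `"burst_fit"`: list with `params`
#'   ([burst_params()]), `rss`, `n_points`, `converged`, `fitted`,
#'   `residuals`, `data`, `init`, `n_starts`.
#' @examples
#' p <- burst_params(1430, 119, 0.027, 25)
#' lt <- seq(40, 240, 20)
#' fit <- fit_burst_model(lt, burst_size(lt, p))
#' coef(fit)
#' @export
fit_burst_model <- function(lysis_time, mean_burst, init = NULL,
                            n_starts = 10L, weights = NULL,
                            max_iter = 200L) {
  lt <- as.numeric(lysis_time)
  y <- as.numeric(mean_burst)
  if (length(lt) != length(y))
    stop("'lysis_time' and 'mean_burst' must have equal length", call. = FALSE)
  ok <- is.finite(lt) & is.finite(y)
  lt <- lt[ok]; y <- y[ok]
  if (length(unique(lt)) < 5L)
    stop("need at least 5 distinct lysis times to identify 4 parameters",
         call. = FALSE)
  if (is.null(weights)) w <- rep(1, length(y))
  else {
    w <- as.numeric(weights)[ok]
    if (any(!is.finite(w)) || any(w < 0))
      stop("'weights' must be finite and nonnegative", call. = FALSE)
  }
  sw <- sqrt(w)

  init <- if (is.null(init)) .auto_init(lt, y) else as_burst_params(init)
  D_hi <- max(lt) * 0.95

  # theta = (log k_max, log(LT50 - D), log r, D)
  to_theta <- function(p) c(log(p$k_max), log(p$LT50 - p$D), log(p$r), p$D)
  from_theta <- function(th) {
    D <- min(max(th[4], 0), D_hi)
    list(k_max = exp(th[1]), LT50 = D + exp(th[2]), r = exp(th[3]), D = D)
  }
  resid_fn <- function(th) {
    p <- from_theta(th)
    sw * (y - burst_size(lt, p))
  }

  # fixed perturbation design (log-scale shifts for the positive parameters,
  # relative shift for D); row 1 is the unperturbed auto-init
  pert <- rbind(
    c(0,     0,    0,    0),
    c(0,     0.4, -0.5,  0),
    c(0,    -0.4,  0.5,  0),
    c(0.3,   0,    0.5, -0.5),
    c(-0.3,  0,   -0.5,  0.5),
    c(0,     0.7,  0,    0.8),
    c(0,    -0.7,  0,   -0.8),
    c(0.3,   0.4,  0.5,  0.5),
    c(-0.3, -0.4, -0.5, -0.5),
    c(0,     0,    1,    0))
  n_starts <- max(1L, min(as.integer(n_starts), nrow(pert)))

  best <- NULL
  th0 <- to_theta(init)
  for (i in seq_len(n_starts)) {
    th_start <- th0 + c(pert[i, 1:3], 0)
    th_start[4] <- min(max(init$D * (1 + pert[i, 4]), 0), D_hi)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th_start, fn = resid_fn,
                         lower = c(-Inf, -Inf, -Inf, 0),
                         upper = c(Inf, Inf, Inf, D_hi),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("all multi-start fits failed", call. = FALSE)

  p <- from_theta(best$fit$par)
  params <- burst_params(p$k_max, p$LT50, p$r, p$D)
  fitted <- burst_size(lt, params)
  structure(list(
    params = params,
    residual_sum_of_squares = best$rss,
    n_points = length(y),
    converged = best$fit$info %in% 1:3,
    fitted = fitted,
    residuals = y - fitted,
    data = data.frame(lysis_time = lt, mean_burst = y, weight = w),
    init = init,
    n_starts = n_starts
  ), class = "burst_fit")
}

.auto_init <- function(lt, y) {
  o <- order(lt)
  lt <- lt[o]; y <- y[o]
  k0 <- max(y)
  pos <- y > 0
  interval <- if (length(unique(lt)) > 1L) stats::median(diff(sort(unique(lt)))) else 10
  D0 <- max(0, min(lt[pos]) - interval)
  half <- k0 / 2
  above <- which(y >= half)
  LT50_0 <- if (length(above) > 0 && above[1] > 1) {
    i <- above[1]
    lt[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (lt[i] - lt[i - 1])
  } else stats::median(lt)
  rising <- pos & y < 0.75 * k0
  r0 <- if (sum(rising) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[rising]) ~ lt[rising]))[2]
    if (is.finite(sl) && sl > 0) unname(sl) else 2 / diff(range(lt))
  } else 2 / diff(range(lt))
  LT50_0 <- max(LT50_0, D0 + interval / 2)
  burst_params(k0, LT50_0, r0, D0)
}

#' @export
print.burst_fit <- function(x, ...) {
  cat("Burst-size model fit (nonlinear least squares)\n")
  print(x$params)
  cat(sprintf("  RSS = %.4g on %d points; converged: %s (%d starts)\n",
              x$residual_sum_of_squares, x$n_points, x$converged, x$n_starts))
  if (!is.null(x$param_cis)) {
    cat("  bootstrap parameter intervals (percentile):\n")
    print(x$param_cis)
  }
  invisible(x)
}

#' @export
coef.burst_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
predict.burst_fit <- function(object, newdata = NULL, ...) {
  lt <- if (is.null(newdata)) object$data$lysis_time
  else if (is.data.frame(newdata)) newdata$lysis_time
  else as.numeric(newdata)
  burst_size(lt, object$params)
}

#' Predicted burst-size curve on a lysis-time grid
#'
#' Evaluates a fitted (or specified) burst-size model on a grid, for plots
#' and residual diagnostics.
#'
#' @param fit A `"burst_fit"` object or [burst_params()].
#' @param grid Lysis times (minutes) at which to evaluate the curve.
#' @return Data frame with columns `lysis_time`, `mean_burst`.
#' @export
predict_curve <- function(fit, grid) {
  params <- if (inherits(fit, "burst_fit")) fit$params else as_burst_params(fit)
  data.frame(lysis_time = grid, mean_burst = burst_size(grid, params))
}

#' Bootstrap parameter intervals by resampling cells within lysis times
#'
#' Attaches percentile bootstrap confidence intervals for the four model
#' parameters to a fit, by resampling occupied wells with replacement
#' within each lysis time, recomputing per-lysis-time means, and refitting
#' from the point estimate. The underlying study reports no fit
#' uncertainty; these intervals are this package's addition and are
#' labelled as such in pipeline output.
#'
#' @param fit A `"burst_fit"` object.
#' @param wells Well-level data frame the fit's means were computed from.
#' @param n_boot Bootstrap replicates (default 200; each requires a refit).
#' @param level Confidence level.
#' @param correction Multiplicative count correction, as in
#'   [summarize_assay()].
#' @return The fit with a `param_cis` data frame (rows `k_max`, `LT50`,
#'   `r`, `D`; columns `lo`, `hi`) added.
#' @export
bootstrap_fit_cis <- function(fit, wells, n_boot = 200L, level = 0.95,
                              correction = 1) {
  stopifnot(inherits(fit, "burst_fit"))
  wells <- validate_wells(wells)
  occupied <- wells[wells$plaque_count > 0, ]
  split_counts <- split(occupied$plaque_count * correction,
                        occupied$lysis_time_min)
  times <- as.numeric(names(split_counts))
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                  dimnames = list(NULL, c("k_max", "LT50", "r", "D")))
  for (b in seq_len(n_boot)) {
    means <- vapply(split_counts, function(x)
      mean(sample(x, length(x), replace = TRUE)), numeric(1))
    fb <- tryCatch(
      fit_burst_model(times, means, init = fit$params, n_starts = 1L),
      error = function(e) NULL)
    if (!is.null(fb)) draws[b, ] <- coef(fb)
  }
  alpha <- (1 - level) / 2
  cis <- t(apply(draws, 2, stats::quantile,
                 probs = c(alpha, 1 - alpha), na.rm = TRUE, type = 1))
  fit$param_cis <- data.frame(lo = cis[, 1], hi = cis[, 2],
                              row.names = rownames(cis))
  fit
}

#' Serialize a burst-size model fit to JSON
#'
#' @param fit A `"burst_fit"` object.
#' @param path Optional output path; if omitted the JSON string is returned.
#' @return JSON string, invisibly when written to `path`.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "burst_fit"))
  obj <- list(
    params = unclass(fit$params),
    residual_sum_of_squares = fit$residual_sum_of_squares,
    n_points = fit$n_points,
    converged = fit$converged,
    n_starts = fit$n_starts)
  if (!is.null(fit$param_cis)) {
    obj$param_cis <- as.list(as.data.frame(t(fit$param_cis)))
    obj$param_cis_note <-
      "bootstrap intervals are a package addition, not reported by the assay"
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
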