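#' Parameters of the saturating burst-size model
#'
#' Container for the four parameters of the sigmoidal relationship between
#' mean burst size and lysis time,
#' \deqn{BS(LT) = k_{max} \frac{e^{r(LT-D)} - 1}{e^{r(LT_{50}-D)} + e^{r(LT-D)} - 2},
#'   \quad LT > D,}{BS(LT) = k_max (exp(r(LT-D)) - 1) /
#'   (exp(r(LT50-D)) + exp(r(LT-D)) - 2), LT > D,}
#' with \eqn{BS = 0} for \eqn{LT \le D}.
#'
#' @param k_max Maximum burst size (PFU/cell); the cellular capacity to
#'   produce phage. Must be positive.
#' @param LT50 Lysis time at which the burst size is half-maximal (minutes).
#'   Must exceed `D`, otherwise the denominator of the model can vanish or
#'   go negative for `LT >= D`.
#' @param r Exponential growth rate of intracellular phage accumulation
#'   (per minute). Must be positive.
#' @param D Time delay before phage start to accumulate (minutes); the burst
#'   size is zero at or before `D`. Must be nonnegative.
#'
#' @return An object of class `"burst_params"`: a named list with components
#'   `k_max`, `LT50`, `r`, `D`.
#'
#' @examples
#' p <- burst_params(k_max = 1430, LT50 = 119, r = 0.027, D = 25)
#' burst_size(c(25, 119, 180), p)
#' @export
burst_params <- function(k_max, LT50, r, D) {
  for (v in list(k_max, LT50, r, D)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("burst-size parameters must be single finite numbers", call. = FALSE)
  }
  if (k_max <= 0) stop("'k_max' must be positive", call. = FALSE)
  if (r <= 0) stop("'r' must be positive", call. = FALSE)
  if (D < 0) stop("'D' must be nonnegative", call. = FALSE)
  if (LT50 <= D) stop("'LT50' must exceed the delay 'D'", call. = FALSE)
  structure(list(k_max = as.numeric(k_max), LT50 = as.numeric(LT50),
                 r = as.numeric(r), D = as.numeric(D)),
            class = "burst_params")
}

#' @export
print.burst_params <- function(x, ...) {
  cat("Burst-size model parameters:\n")
  cat(sprintf("  k_max = %g PFU/cell\n  LT50  = %g min\n  r     = %g /min\n  D     = %g min\n",
              x$k_max, x$LT50, x$r, x$D))
  invisible(x)
}

as_burst_params <- function(x) {
  if (inherits(x, "burst_params")) return(x)
  if (is.list(x) && all(c("k_max", "LT50", "r", "D") %in% names(x)))
    return(burst_params(x$k_max, x$LT50, x$r, x$D))
  if (is.numeric(x) && length(x) == 4L && !is.null(names(x)))
    return(burst_params(x[["k_max"]], x[["LT50"]], x[["r"]], x[["D"]]))
  stop("cannot interpret 'params' as burst-size parameters", call. = FALSE)
}

#' Cell-to-cell noise budget for the burst-size parameters
#'
#' Squared coefficients of variation (CV^2) quantifying cell-to-cell
#' variability of each burst-size model parameter. These are the inputs to
#' the first-order decomposition of burst-size noise in [cv2_burst()]. The
#' delay `D` is treated as fixed across cells.
#'
#' @param cv2_kmax,cv2_LT50,cv2_r Nonnegative squared coefficients of
#'   variation (dimensionless) of `k_max`, `LT50` and `r` across cells.
#'
#' @return An object of class `"noise_budget"`.
#' @examples
#' noise_budget(cv2_kmax = 0.16)
#' @export
noise_budget <- function(cv2_kmax = 0, cv2_LT50 = 0, cv2_r = 0) {
  v <- c(cv2_kmax = cv2_kmax, cv2_LT50 = cv2_LT50, cv2_r = cv2_r)
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
    stop("noise-budget components must be finite and nonnegative", call. = FALSE)
  structure(as.list(v), class = "noise_budget")
}

#' @export
print.noise_budget <- function(x, ...) {
  cat(sprintf("Noise budget (CV^2): k_max = %g, LT50 = %g, r = %g\n",
              x$cv2_kmax, x$cv2_LT50, x$cv2_r))
  invisible(x)
}

as_noise_budget <- function(x) {
  if (inherits(x, "noise_budget")) return(x)
  if (is.list(x) || (is.numeric(x) && !is.null(names(x))))
    return(noise_budget(
      cv2_kmax = if (!is.null(x[["cv2_kmax"]])) x[["cv2_kmax"]] else 0,
      cv2_LT50 = if (!is.null(x[["cv2_LT50"]])) x[["cv2_LT50"]] else 0,
      cv2_r    = if (!is.null(x[["cv2_r"]]))    x[["cv2_r"]]    else 0))
  stop("cannot interpret 'budget' as a noise budget", call. = FALSE)
}

# Overflow-safe scaled exponentials shared by burst_size() and
# burst_sensitivities(): all exponentials are divided by exp(m), m =
# max(a, b, 0), so no intermediate exceeds 1 even when r*(LT - D) is in the
# thousands (naive exp() overflows past ~709).
.burst_scaled <- function(lt, p) {
  a <- p$r * (lt - p$D)
  b <- p$r * (p$LT50 - p$D)
  m <- pmax(a, b, 0)
  ea <- exp(a - m)
  eb <- exp(b - m)
  e0 <- exp(-m)
  list(a = a, b = b, ea = ea, eb = eb, e0 = e0,
       den = eb + ea - 2 * e0)
}

#' Mean burst size as a function of lysis time
#'
#' Evaluates the saturating burst-size model (see [burst_params()]) at one
#' or more lysis times. The function is zero for `lysis_time <= D`,
#' increases monotonically, equals `k_max / 2` at `LT50`, and approaches
#' `k_max` as the lysis time grows. Exponentials are evaluated in a scaled
#' form so that very large `r * (lysis_time - D)` cannot overflow.
#'
#' @param lysis_time Numeric vector of lysis times (minutes), nonnegative.
#' @param params A [burst_params()] object (or coercible list).
#'
#' @return Numeric vector of mean burst sizes (PFU/cell).
#' @examples
#' p <- burst_params(1430, 119, 0.027, 25)
#' burst_size(119, p)  # exactly k_max / 2
#' @export
burst_size <- function(lysis_time, params) {
  p <- as_burst_params(params)
  lt <- as.numeric(lysis_time)
  if (length(lt) == 0L) return(numeric(0))
  if (any(!is.finite(lt)) || any(lt < 0))
    stop("'lysis_time' must be finite and nonnegative", call. = FALSE)
  s <- .burst_scaled(lt, p)
  out <- numeric(length(lt))
  pos <- lt > p$D
  out[pos] <- p$k_max * (s$ea[pos] - s$e0[pos]) / s$den[pos]
  out
}

#' Dimensionless log-sensitivities of the burst-size model
#'
#' Elasticities \eqn{S_x = (x / f) \, \partial f / \partial x} of the mean
#' burst size \eqn{f} with respect to `k_max`, `LT50` and `r`, evaluated
#' analytically. The capacity sensitivity is identically 1 at every lysis
#' time, while the `LT50` and `r` sensitivities decay to 0 at long lysis
#' times; this asymmetry is what lets a flat burst-size CV^2 profile
#' discriminate capacity heterogeneity from lysis-kinetics heterogeneity.
#'
#' @inheritParams burst_size
#' @return A data frame with columns `lysis_time`, `S_kmax`, `S_LT50`,
#'   `S_r`, one row per lysis time.
#' @seealso [cv2_burst()] for the noise decomposition these feed.
#' @examples
#' burst_sensitivities(c(60, 240), burst_params(1430, 119, 0.027, 25))
#' @export
burst_sensitivities <- function(lysis_time, params) {
  p <- as_burst_params(params)
  lt <- as.numeric(lysis_time)
  if (any(!is.finite(lt)) || any(lt <= p$D))
    stop("log-sensitivities are undefined for lysis_time <= D (zero burst size)",
         call. = FALSE)
  s <- .burst_scaled(lt, p)
  S_LT50 <- -p$r * p$LT50 * s$eb / s$den
  # S_r = r * [ (LT-D) e^a / (e^a - 1) - ((LT50-D) e^b + (LT-D) e^a) / den ];
  # e^a/(e^a - 1) = 1/(1 - e^(-a)) uses expm1 for accuracy at small a
  term1 <- (lt - p$D) / (-expm1(-s$a))
  term2 <- ((p$LT50 - p$D) * s$eb + (lt - p$D) * s$ea) / s$den
  S_r <- p$r * (term1 - term2)
  data.frame(lysis_time = lt, S_kmax = rep(1, length(lt)),
             S_LT50 = S_LT50, S_r = S_r)
}

#' First-order decomposition of burst-size noise
#'
#' Squared coefficient of variation of the burst size predicted from
#' cell-to-cell variability in the model parameters, by first-order
#' (small-fluctuation) propagation:
#' \deqn{CV^2_{BS} = S_{k_{max}}^2 CV^2_{k_{max}} + S_{LT_{50}}^2 CV^2_{LT_{50}}
#'   + S_r^2 CV^2_r,}
#' with the log-sensitivities of [burst_sensitivities()]. Parameters are
#' assumed independent across cells (no covariance terms). Because the
#' capacity sensitivity is identically 1, a budget containing only
#' `cv2_kmax` predicts a CV^2 that is constant in lysis time, whereas
#' `LT50`- or `r`-only budgets predict CV^2 decaying to zero at long lysis
#' times.
#'
#' @inheritParams burst_size
#' @param budget A [noise_budget()] object (or coercible list).
#' @return Numeric vector of predicted burst-size CV^2, one per lysis time.
#' @examples
#' p <- burst_params(1430, 119, 0.027, 25)
#' cv2_burst(c(60, 240), p, noise_budget(cv2_kmax = 0.16))   # flat
#' cv2_burst(c(60, 240), p, noise_budget(cv2_LT50 = 0.16))   # decaying
#' @export
cv2_burst <- function(lysis_time, params, budget) {
  b <- as_noise_budget(budget)
  S <- burst_sensitivities(lysis_time, params)
  S$S_kmax^2 * b$cv2_kmax + S$S_LT50^2 * b$cv2_LT50 + S$S_r^2 * b$cv2_r
}

#' Serialize model parameters and noise budget to flat JSON
#'
#' Writes (or renders) a flat JSON object with keys `k_max`, `LT50`, `r`,
#' `D` and, when a budget is supplied, `cv2_kmax`, `cv2_LT50`, `cv2_r`.
#'
#' @param params A [burst_params()] object.
#' @param budget Optional [noise_budget()] object.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_model_json <- function(params, budget = NULL, path = NULL) {
  p <- as_burst_params(params)
  obj <- list(k_max = p$k_max, LT50 = p$LT50, r = p$r, D = p$D)
  if (!is.null(budget)) {
    b <- as_noise_budget(budget)
    obj <- c(obj, list(cv2_kmax = b$cv2_kmax, cv2_LT50 = b$cv2_LT50,
                       cv2_r = b$cv2_r))
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read model parameters (and optional noise budget) from flat JSON
#'
#' @param path Path to a JSON file, or a JSON string, as written by
#'   [write_model_json()].
#' @return A list with components `params` ([burst_params()]) and `budget`
#'   ([noise_budget()] or `NULL` when no CV^2 keys are present).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  params <- burst_params(obj$k_max, obj$LT50, obj$r, obj$D)
  budget <- NULL
  if (any(c("cv2_kmax", "cv2_LT50", "cv2_r") %in% names(obj)))
    budget <- as_noise_budget(obj)
  list(params = params, budget = budget)
}
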