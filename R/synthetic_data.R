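#' Configuration of a synthetic limiting-dilution burst-size assay
#'
#' Fully specifies a simulated plate experiment: plate geometry, Poisson
#' cell occupancy, the lysis-time schedule, the population-mean burst-size
#' parameters, the cell-to-cell heterogeneity of those parameters, the
#' lysis mode, and binomial virion-viability thinning.
#'
#' Defaults reproduce the structure of the real assay: 96-well plates at
#' 0.25 cells/well, around five plates (so ~500 wells, ~100 occupied) per
#' lysis time, chemical lysis on a 40-240 min schedule, population
#' parameters at the fitted values (k_max = 1430 PFU/cell, LT50 = 119 min,
#' r = 0.027/min, D = 25 min), capacity-only heterogeneity with
#' CV^2(k_max) = 0.16 (CV 0.4), and a per-virion survival probability of
#' 0.81 reflecting the measured 19% loss of countable phage under the
#' chloroform protocol.
#'
#' @param n_plates_per_timepoint Plates simulated per lysis time.
#' @param n_wells Wells per plate.
#' @param mean_occupancy Mean cells per well (Poisson rate).
#' @param lysis_times Chemical lysis schedule in minutes.
#' @param true_params Population-mean [burst_params()].
#' @param heterogeneity [noise_budget()] of per-cell parameter CV^2s; `D`
#'   is fixed across cells.
#' @param parameter_family Distribution of per-cell parameters:
#'   `"lognormal"` (default) or `"gamma"`, both moment-matched to the
#'   configured mean and CV.
#' @param lysis_mode `"chemical"` (every cell lysed exactly at the
#'   scheduled time) or `"natural"` (per-cell lysis times drawn from a
#'   normal distribution truncated at `> D`).
#' @param natural_lt_mean,natural_lt_cv Mean (minutes) and CV of natural
#'   lysis times (defaults 40.89 min and 0.05; lysis-time noise is an order
#'   of magnitude smaller than burst-size noise).
#' @param viability Per-virion probability of producing a plaque
#'   (binomial thinning; default 0.81).
#' @param seed Integer seed making [simulate_experiment()] deterministic.
#' @return An object of class `"assay_config"`.
#' @examples
#' cfg <- assay_config(n_plates_per_timepoint = 2, seed = 1)
#' sim <- simulate_experiment(cfg)
#' head(sim$wells)
#' @export
assay_config <- function(n_plates_per_timepoint = 5L,
                         n_wells = 96L,
                         mean_occupancy = 0.25,
                         lysis_times = seq(40, 240, by = 20),
                         true_params = burst_params(1430, 119, 0.027, 25),
                         heterogeneity = noise_budget(cv2_kmax = 0.16),
                         parameter_family = c("lognormal", "gamma"),
                         lysis_mode = c("chemical", "natural"),
                         natural_lt_mean = 40.89,
                         natural_lt_cv = 0.05,
                         viability = 0.81,
                         seed = 1L) {
  parameter_family <- match.arg(parameter_family)
  lysis_mode <- match.arg(lysis_mode)
  true_params <- as_burst_params(true_params)
  heterogeneity <- as_noise_budget(heterogeneity)
  if (n_plates_per_timepoint < 1)
    stop("'n_plates_per_timepoint' must be at least 1", call. = FALSE)
  if (n_wells < 1) stop("'n_wells' must be at least 1", call. = FALSE)
  if (mean_occupancy < 0)
    stop("'mean_occupancy' must be nonnegative", call. = FALSE)
  if (length(lysis_times) < 1L || any(lysis_times <= 0))
    stop("'lysis_times' must be positive", call. = FALSE)
  if (viability <= 0 || viability > 1)
    stop("'viability' must be in (0, 1]", call. = FALSE)
  if (lysis_mode == "natural" &&
      (natural_lt_mean <= true_params$D || natural_lt_cv < 0))
    stop("natural lysis needs mean lysis time > D and nonnegative CV",
         call. = FALSE)
  structure(list(
    n_plates_per_timepoint = as.integer(n_plates_per_timepoint),
    n_wells = as.integer(n_wells),
    mean_occupancy = mean_occupancy,
    lysis_times = as.numeric(lysis_times),
    true_params = true_params,
    heterogeneity = heterogeneity,
    parameter_family = parameter_family,
    lysis_mode = lysis_mode,
    natural_lt_mean = natural_lt_mean,
    natural_lt_cv = natural_lt_cv,
    viability = viability,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "assay_config")
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic assay: %d plate(s) x %d wells per timepoint, %g cells/well\n",
    x$n_plates_per_timepoint, x$n_wells, x$mean_occupancy))
  cat(sprintf("  lysis: %s at {%s} min; viability %g; family %s; seed %s\n",
              x$lysis_mode, paste(x$lysis_times, collapse = ", "),
              x$viability, x$parameter_family,
              if (is.null(x$seed)) "none" else x$seed))
  print(x$true_params)
  print(x$heterogeneity)
  invisible(x)
}

# moment-matched positive draws with mean m and squared CV v
.draw_positive <- function(n, m, v, family) {
  if (v == 0) return(rep(m, n))
  if (family == "lognormal") {
    sdlog <- sqrt(log1p(v))
    stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    stats::rgamma(n, shape = 1 / v, scale = m * v)
  }
}

#' Draw per-cell burst-size parameters
#'
#' Samples `n` cells' parameters independently from the configured
#' heterogeneity: `k_max`, `LT50` and `r` from a moment-matched lognormal
#' (or gamma) with the population mean and the CV implied by the noise
#' budget; the delay `D` is identical across cells. Components with zero
#' CV^2 return the population mean exactly.
#'
#' @param n Number of cells.
#' @param config An [assay_config()].
#' @return Data frame with `n` rows and columns `k_max`, `LT50`, `r`, `D`.
#' @export
draw_cell_params <- function(n, config) {
  stopifnot(inherits(config, "assay_config"))
  p <- config$true_params
  h <- config$heterogeneity
  fam <- config$parameter_family
  data.frame(
    k_max = .draw_positive(n, p$k_max, h$cv2_kmax, fam),
    LT50 = .draw_positive(n, p$LT50, h$cv2_LT50, fam),
    r = .draw_positive(n, p$r, h$cv2_r, fam),
    D = rep(p$D, n))
}

# per-cell lysis times for one timepoint; natural lysis truncated at > D
.draw_lysis_times <- function(n, config, scheduled_lt) {
  if (config$lysis_mode == "chemical" || n == 0L)
    return(rep(scheduled_lt, n))
  mu <- config$natural_lt_mean
  sd <- config$natural_lt_cv * mu
  if (sd == 0) return(rep(mu, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mu, sd)
    ok <- draw > config$true_params$D
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# burst_size generalised to per-cell parameter vectors, with the same
# scaled-exponential overflow guard
.burst_size_cells <- function(lt, cp) {
  a <- cp$r * (lt - cp$D)
  b <- cp$r * (cp$LT50 - cp$D)
  m <- pmax(a, b, 0)
  ea <- exp(a - m)
  e0 <- exp(-m)
  out <- cp$k_max * (ea - e0) / (exp(b - m) + ea - 2 * e0)
  out[lt <= cp$D] <- 0
  out
}

# vectorised core: simulate all wells of one plate at one scheduled lysis
# time; returns integer plaque counts and latent cell counts
.simulate_plate <- function(config, scheduled_lt) {
  nw <- config$n_wells
  n_cells <- stats::rpois(nw, config$mean_occupancy)
  total <- sum(n_cells)
  plaques <- integer(nw)
  if (total > 0) {
    cell_well <- rep.int(seq_len(nw), n_cells)
    cp <- draw_cell_params(total, config)
    lt_cell <- .draw_lysis_times(total, config, scheduled_lt)
    bursts <- round(.burst_size_cells(lt_cell, cp))
    per_well <- vapply(split(bursts, factor(cell_well, levels = seq_len(nw))),
                       sum, numeric(1))
    plaques <- stats::rbinom(nw, size = as.integer(per_well),
                             prob = config$viability)
  }
  list(n_cells = n_cells, plaque_count = plaques)
}

#' Simulate a single well
#'
#' Draws the cell count from the Poisson occupancy, gives each cell its own
#' parameters and lysis time, rounds each cell's burst to whole virions,
#' and thins the pooled burst binomially by the per-virion viability. Uses
#' the current RNG stream.
#'
#' @param config An [assay_config()].
#' @param lysis_time Scheduled (chemical) lysis time for this well, minutes.
#' @return A list with `n_cells` (latent truth) and `plaque_count`.
#' @export
simulate_well <- function(config, lysis_time) {
  stopifnot(inherits(config, "assay_config"))
  cfg1 <- config
  cfg1$n_wells <- 1L
  res <- .simulate_plate(cfg1, lysis_time)
  list(n_cells = res$n_cells[1], plaque_count = res$plaque_count[1])
}

#' Simulate a complete limiting-dilution assay
#'
#' Runs [simulate_well()] logic over every plate, well and lysis time of
#' the configuration. Deterministic given `config$seed`. The returned well
#' table keeps the latent true cell count for truth-tracking; use
#' [write_assay_csv()] to emit the analysis-facing CSV, which drops it.
#'
#' @param config An [assay_config()].
#' @return An object of class `"assay_sim"`: list with `wells` (data frame
#'   `plate`, `well`, `lysis_time_min`, `n_cells`, `plaque_count`) and
#'   `truth` (config echo plus per-timepoint model-implied mean burst sizes
#'   and first-order CV^2 predictions).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  blocks <- list()
  idx <- 1L
  for (tt in config$lysis_times) {
    for (pl in seq_len(config$n_plates_per_timepoint)) {
      res <- .simulate_plate(config, tt)
      blocks[[idx]] <- data.frame(
        plate = sprintf("LT%03d_P%02d", as.integer(round(tt)), pl),
        well = .well_ids(config$n_wells),
        lysis_time_min = tt,
        n_cells = res$n_cells,
        plaque_count = res$plaque_count)
      idx <- idx + 1L
    }
  }
  wells <- do.call(rbind, blocks)
  rownames(wells) <- NULL
  eff_lt <- if (config$lysis_mode == "chemical") config$lysis_times
  else rep(config$natural_lt_mean, length(config$lysis_times))
  truth <- list(
    config = config,
    per_timepoint = data.frame(
      lysis_time_min = config$lysis_times,
      true_mean_burst = burst_size(eff_lt, config$true_params),
      true_mean_counted = burst_size(eff_lt, config$true_params) *
        config$viability,
      predicted_cv2 = cv2_burst(eff_lt, config$true_params,
                                config$heterogeneity)))
  structure(list(wells = wells, truth = truth), class = "assay_sim")
}

.well_ids <- function(n_wells) {
  rows <- LETTERS[1:8]
  ids <- as.vector(t(outer(rows, 1:12, function(r, c) paste0(r, c))))
  if (n_wells <= 96L) ids[seq_len(n_wells)]
  else sprintf("W%03d", seq_len(n_wells))
}

#' @export
print.assay_sim <- function(x, ...) {
  occ <- x$wells$plaque_count > 0
  cat(sprintf("Simulated assay: %d wells (%d occupied by plaque count) at %d lysis times\n",
              nrow(x$wells), sum(occ),
              length(unique(x$wells$lysis_time_min))))
  invisible(x)
}

#' Write the truth sidecar of a simulated assay
#'
#' JSON record of the generating configuration and the per-timepoint
#' model-implied mean burst sizes and first-order CV^2 predictions; kept
#' separate from the analysis CSV so latent truth never leaks into the
#' analysis inputs.
#'
#' @param sim An `"assay_sim"` object.
#' @param path Output JSON path.
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "assay_sim"))
  cfg <- sim$truth$config
  obj <- list(
    config = list(
      n_plates_per_timepoint = cfg$n_plates_per_timepoint,
      n_wells = cfg$n_wells,
      mean_occupancy = cfg$mean_occupancy,
      lysis_times = cfg$lysis_times,
      true_params = unclass(cfg$true_params),
      heterogeneity = unclass(cfg$heterogeneity),
      parameter_family = cfg$parameter_family,
      lysis_mode = cfg$lysis_mode,
      natural_lt_mean = cfg$natural_lt_mean,
      natural_lt_cv = cfg$natural_lt_cv,
      viability = cfg$viability,
      seed = cfg$seed),
    per_timepoint = sim$truth$per_timepoint)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
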