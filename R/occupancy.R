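#' Limiting-dilution plate design
#'
#' Geometry of a limiting-dilution assay: wells per plate and the target
#' mean cell occupancy per well. Under limiting dilution the number of cells
#' per well is Poisson distributed, so the empty-well fraction and the
#' multi-cell fraction follow directly from the mean occupancy.
#'
#' @param n_wells Number of wells per plate (default 96).
#' @param mean_occupancy Mean number of cells per well (Poisson rate
#'   \eqn{\lambda}), nonnegative.
#' @return An object of class `"plate_design"`.
#' @examples
#' plate_design(96, 0.25)
#' @export
plate_design <- function(n_wells = 96L, mean_occupancy = 0.25) {
  if (!is.numeric(n_wells) || length(n_wells) != 1L || n_wells < 1 ||
      n_wells != round(n_wells))
    stop("'n_wells' must be a positive integer", call. = FALSE)
  if (!is.numeric(mean_occupancy) || length(mean_occupancy) != 1L ||
      !is.finite(mean_occupancy) || mean_occupancy < 0)
    stop("'mean_occupancy' must be a finite nonnegative number", call. = FALSE)
  structure(list(n_wells = as.integer(n_wells),
                 mean_occupancy = as.numeric(mean_occupancy)),
            class = "plate_design")
}

#' @export
print.plate_design <- function(x, ...) {
  cat(sprintf("Limiting-dilution design: %d wells, %g cells/well (Poisson)\n",
              x$n_wells, x$mean_occupancy))
  cat(sprintf("  expected empty wells: %.2f (%.0f%% of wells)\n",
              expected_empty(x), 100 * exp(-x$mean_occupancy)))
  invisible(x)
}

#' Probability that a well receives k cells
#'
#' Poisson probability mass function for the number of cells deposited in a
#' well under limiting dilution.
#'
#' @param k Nonnegative integer cell count(s).
#' @param mean_occupancy Mean cells per well (\eqn{\lambda \ge 0}).
#' @return Probabilities, same length as `k`.
#' @examples
#' p_cells(2, 0.25)  # ~2% of wells receive exactly two cells
#' p_cells(2, 0.61)  # ~10% at the highest observed occupancy
#' @export
p_cells <- function(k, mean_occupancy) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0) || any(k != round(k)))
    stop("'k' must be nonnegative integer(s)", call. = FALSE)
  if (!is.numeric(mean_occupancy) || any(!is.finite(mean_occupancy)) ||
      any(mean_occupancy < 0))
    stop("'mean_occupancy' must be nonnegative", call. = FALSE)
  stats::dpois(k, mean_occupancy)
}

#' Expected number of empty wells on a plate
#'
#' @param design A [plate_design()] object.
#' @return `n_wells * exp(-mean_occupancy)` (not rounded). Taking the floor
#'   gives the whole-well count quoted for assay planning: 74 of 96 wells at
#'   0.25 cells/well, 52 at 0.61.
#' @examples
#' floor(expected_empty(plate_design(96, 0.25)))  # 74
#' @export
expected_empty <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  design$n_wells * exp(-design$mean_occupancy)
}

#' Estimate mean occupancy from the observed empty-well count
#'
#' Poisson zero-class estimator: if a fraction `n_empty / n_wells` of wells
#' produced no plaques, the implied mean occupancy is
#' \eqn{-\log(n_{empty}/n_{wells})}.
#'
#' @param n_empty Observed number of empty wells (must be positive; with no
#'   empty wells the occupancy is not estimable from the zero class).
#' @param n_wells Total number of wells.
#' @return Estimated mean cells per well.
#' @examples
#' occupancy_from_empty(52, 96)  # ~0.61 cells/well
#' @export
occupancy_from_empty <- function(n_empty, n_wells) {
  if (!is.numeric(n_empty) || !is.numeric(n_wells) ||
      length(n_empty) != 1L || length(n_wells) != 1L)
    stop("'n_empty' and 'n_wells' must be single numbers", call. = FALSE)
  if (n_wells < 1 || n_empty > n_wells)
    stop("'n_empty' must not exceed 'n_wells'", call. = FALSE)
  if (n_empty <= 0)
    stop("occupancy is not estimable when no wells are empty", call. = FALSE)
  -log(n_empty / n_wells)
}

#' Fraction of occupied wells containing more than one cell
#'
#' Conditional probability \eqn{P(N \ge 2 \mid N \ge 1)} under Poisson
#' occupancy; the burst sizes from such wells sit in the right tail of the
#' observed distribution and drive its right skew.
#'
#' @param mean_occupancy Mean cells per well (> 0).
#' @return Probability that an occupied well holds two or more cells.
#' @examples
#' p_multicell_given_occupied(0.61)
#' @export
p_multicell_given_occupied <- function(mean_occupancy) {
  if (!is.numeric(mean_occupancy) || any(mean_occupancy <= 0))
    stop("'mean_occupancy' must be positive", call. = FALSE)
  p_occ <- -expm1(-mean_occupancy)
  (p_occ - mean_occupancy * exp(-mean_occupancy)) / p_occ
}

#' Well-occupancy summary for a design, in paper-style percent
#'
#' @param design A [plate_design()] object.
#' @param k_max_cells Largest cell count to tabulate individually.
#' @return Data frame with cell count, probability, nearest-integer percent
#'   of wells, and expected wells per plate.
#' @export
occupancy_table <- function(design, k_max_cells = 3L) {
  stopifnot(inherits(design, "plate_design"))
  k <- 0:k_max_cells
  p <- p_cells(k, design$mean_occupancy)
  data.frame(n_cells = k, probability = p,
             percent_of_wells = round(100 * p),
             expected_wells = design$n_wells * p)
}
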