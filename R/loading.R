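# Poisson occupancy mathematics for droplet loading design.
#
# Cells suspended at density rho (cells per unit volume) partitioned into
# droplets of volume V land in any given droplet as Poisson(nbar) with
# nbar = rho * V.  All loading design reduces to arithmetic on that law.

#' Poisson droplet occupancy probability
#'
#' Probability that a droplet contains exactly `n` cells when cells are
#' encapsulated at a mean occupancy of `mean_occupancy` cells per droplet.
#'
#' @param mean_occupancy Expected number of cells per droplet
#'   (dimensionless, non-negative); the product of cell density and
#'   droplet volume.
#' @param n Number of cells in the droplet (non-negative integer, vectorised).
#' @return Numeric vector of probabilities, one per element of `n`.
#' @examples
#' occupancy_pmf(0.1, 0)   # fraction of empty droplets, ~0.905
#' occupancy_pmf(0.3, 0:3)
#' @export
occupancy_pmf <- function(mean_occupancy, n) {
  if (!is.numeric(mean_occupancy) || length(mean_occupancy) != 1L ||
      !is.finite(mean_occupancy) || mean_occupancy < 0) {
    stop("'mean_occupancy' must be a single finite number >= 0")
  }
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) ||
      any(n != floor(n))) {
    stop("'n' must contain non-negative integers")
  }
  stats::dpois(n, lambda = mean_occupancy)
}

#' Summarise droplet occupancy at a given mean loading
#'
#' Computes the standard loading trade-off quantities for Poisson
#' encapsulation: the fraction of droplets that are empty, loaded (>= 1
#' cell), clonally loaded (exactly 1 cell), or multiply loaded (>= 2 cells),
#' together with the fraction of loaded droplets that are clonal.  Droplet
#' assays balance the number of occupied droplets against the contamination
#' from multi-cell droplets by choosing `mean_occupancy`, typically in the
#' 0.1--0.3 range.
#'
#' @inheritParams occupancy_pmf
#' @return An object of class `"loading_summary"`: a list with elements
#'   `mean_occupancy`, `p_empty`, `p_loaded`, `p_single`, `p_multi`, and
#'   `p_single_given_loaded`.
#' @examples
#' loading_summary(0.3)  # ~26% loaded, ~86% of loaded droplets clonal
#' loading_summary(0.1)  # ~10% loaded, ~95% of loaded droplets clonal
#' @export
loading_summary <- function(mean_occupancy) {
  if (!is.numeric(mean_occupancy) || length(mean_occupancy) != 1L ||
      !is.finite(mean_occupancy) || mean_occupancy <= 0) {
    stop("'mean_occupancy' must be a single finite number > 0 ",
         "(at 0 no droplet is ever loaded and the clonal fraction ",
         "of loaded droplets is undefined)")
  }
  p_empty  <- exp(-mean_occupancy)
  p_single <- mean_occupancy * exp(-mean_occupancy)
  p_loaded <- 1 - p_empty
  out <- list(
    mean_occupancy = mean_occupancy,
    p_empty = p_empty,
    p_loaded = p_loaded,
    p_single = p_single,
    p_multi = p_loaded - p_single,
    p_single_given_loaded = p_single / p_loaded
  )
  class(out) <- "loading_summary"
  out
}

#' @export
print.loading_summary <- function(x, digits = 4, ...) {
  cat("Poisson droplet loading at mean occupancy",
      format(x$mean_occupancy, digits = digits), "\n")
  fields <- c(p_empty = "empty", p_loaded = "loaded (>=1 cell)",
              p_single = "single cell", p_multi = "multiple cells (>=2)",
              p_single_given_loaded = "single | loaded")
  for (f in names(fields)) {
    cat(sprintf("  %-22s %6.2f%%\n", fields[[f]], 100 * x[[f]]))
  }
  invisible(x)
}

#' Cell density required to hit a target mean occupancy
#'
#' Converts a target mean droplet occupancy into the cell density of the
#' suspension to be encapsulated, `rho = K * nbar / V`, where `K` is an
#' empirically determined constant converting CFU counts per ml to OD600
#' (from replicate plating of the same suspension).  `droplet_volume` must
#' be expressed in the volume unit of the density (ml if `cell_density`
#' is per ml).
#'
#' @inheritParams occupancy_pmf
#' @param droplet_volume Volume of a single droplet (> 0).
#' @param od_cfu_constant Conversion constant `K` from CFU/volume to OD600
#'   (> 0).  Determined empirically per organism/suspension; no default.
#' @return Target cell density (same volume unit as `droplet_volume`).
#' @examples
#' dilution_for_target(0.2, droplet_volume = 1e-7, od_cfu_constant = 1)
#' @export
dilution_for_target <- function(mean_occupancy, droplet_volume,
                                od_cfu_constant) {
  args <- c(mean_occupancy = mean_occupancy,
            droplet_volume = droplet_volume,
            od_cfu_constant = od_cfu_constant)
  if (!is.numeric(args) || length(args) != 3L || any(!is.finite(args)) ||
      any(args <= 0)) {
    stop("'mean_occupancy', 'droplet_volume' and 'od_cfu_constant' must ",
         "all be single positive finite numbers")
  }
  od_cfu_constant * mean_occupancy / droplet_volume
}

#' Infer mean occupancy from the observed fraction of empty droplets
#'
#' Under Poisson loading the empty fraction is `exp(-nbar)`, so counting
#' empty droplets under a microscope identifies the realised mean occupancy
#' as `-log(f_empty)` without any knowledge of the cell density.
#'
#' @param f_empty Observed fraction of empty droplets, in (0, 1].
#' @return Inferred mean occupancy (cells per droplet).
#' @examples
#' infer_mean_from_empty_fraction(0.74)  # ~0.301
#' @export
infer_mean_from_empty_fraction <- function(f_empty) {
  if (!is.numeric(f_empty) || length(f_empty) != 1L || !is.finite(f_empty) ||
      f_empty > 1 || f_empty < 0) {
    stop("'f_empty' must be a single fraction in (0, 1]")
  }
  if (f_empty == 0) {
    stop("an empty fraction of 0 implies infinite mean occupancy")
  }
  -log(f_empty)
}

#' Mean occupancy that yields a target fraction of single-cell droplets
#'
#' Solves `nbar * exp(-nbar) = target_p_single` for the mean occupancy.
#' The single-cell fraction peaks at `exp(-1)` (at `nbar = 1`), so any
#' attainable target has two roots; the smaller, dilution-regime root is
#' returned by default since loading protocols dilute toward clonality.
#' The multi-cell fraction implied by the chosen root is reported
#' alongside: protocols targeting ~20% clonal droplets incur a multi-cell
#' droplet fraction just under 3%.
#'
#' @param target_p_single Desired fraction of all droplets containing
#'   exactly one cell, in (0, exp(-1)].
#' @param upper_branch If `TRUE`, return the larger (overloading-regime)
#'   root instead of the smaller one.
#' @return A list with elements `mean_occupancy`, `p_single` (the achieved
#'   target) and `p_multi` (implied fraction of droplets with >= 2 cells).
#' @examples
#' mean_for_single_fraction(0.2)  # nbar ~0.259, p_multi ~2.8%
#' @export
mean_for_single_fraction <- function(target_p_single, upper_branch = FALSE) {
  if (!is.numeric(target_p_single) || length(target_p_single) != 1L ||
      !is.finite(target_p_single) || target_p_single <= 0) {
    stop("'target_p_single' must be a single positive number")
  }
  if (target_p_single > exp(-1)) {
    stop("infeasible target: the single-cell fraction cannot exceed ",
         "exp(-1) ~= ", format(exp(-1), digits = 4))
  }
  f <- function(nbar) nbar * exp(-nbar) - target_p_single
  if (upper_branch) {
    lo <- 1
    hi <- 2
    while (f(hi) > 0) hi <- hi * 2  # f decreasing beyond nbar = 1
  } else {
    lo <- 0
    hi <- 1
  }
  # bisection: f is monotone on each branch, tolerance on nbar
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (hi - lo < 1e-12) break
    # on the lower branch f is increasing, on the upper decreasing
    rising <- !upper_branch
    if ((f(mid) > 0) == rising) hi <- mid else lo <- mid
  }
  nbar <- (lo + hi) / 2
  list(
    mean_occupancy = nbar,
    p_single = nbar * exp(-nbar),
    p_multi = 1 - exp(-nbar) - nbar * exp(-nbar)
  )
}

#' Droplet loading specification
#'
#' Bundles the quantities that define a loading protocol: mean occupancy
#' `nbar`, droplet volume `V`, CFU-to-OD conversion constant `K` and cell
#' density `rho`, related by `rho = K * nbar / V`.  Exactly one of
#' `mean_occupancy` or `cell_density` may be omitted and is filled in from
#' the identity; if all four are supplied the identity is checked.
#'
#' @param mean_occupancy Expected cells per droplet (>= 0), or `NULL`.
#' @param droplet_volume Droplet volume (> 0), in the volume unit of
#'   `cell_density`.
#' @param od_cfu_constant Conversion constant `K` (> 0).
#' @param cell_density Cell density of the suspension (>= 0), or `NULL`.
#' @return A list of class `"loading_spec"` with the four fields populated.
#' @export
loading_spec <- function(mean_occupancy = NULL, droplet_volume,
                         od_cfu_constant, cell_density = NULL) {
  if (droplet_volume <= 0) stop("'droplet_volume' must be > 0")
  if (od_cfu_constant <= 0) stop("'od_cfu_constant' must be > 0")
  if (is.null(mean_occupancy) && is.null(cell_density)) {
    stop("supply at least one of 'mean_occupancy' and 'cell_density'")
  }
  if (is.null(mean_occupancy)) {
    mean_occupancy <- cell_density * droplet_volume / od_cfu_constant
  } else if (is.null(cell_density)) {
    cell_density <- od_cfu_constant * mean_occupancy / droplet_volume
  } else {
    implied <- od_cfu_constant * mean_occupancy / droplet_volume
    if (abs(implied - cell_density) >
        1e-8 * max(1, abs(cell_density))) {
      stop("inconsistent loading spec: rho != K * nbar / V")
    }
  }
  if (mean_occupancy < 0) stop("'mean_occupancy' must be >= 0")
  structure(
    list(mean_occupancy = mean_occupancy, droplet_volume = droplet_volume,
         od_cfu_constant = od_cfu_constant, cell_density = cell_density),
    class = "loading_spec"
  )
}
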