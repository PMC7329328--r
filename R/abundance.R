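# From raw observations (SV read counts + total 16S qPCR) to filtered
# absolute-abundance tables.  Tables are plain numeric matrices with
# samples in rows (rownames = sample ids) and SVs in columns.

#' Drop shallowly sequenced samples
#'
#' Retains only samples whose total read count is strictly greater than
#' `min_reads`, removing outlying samples likely affected by library
#' preparation or sequencing artifacts.
#'
#' @param counts Integer matrix of read counts, samples x SVs, with sample
#'   ids as rownames.
#' @param min_reads Depth cutoff; samples with total reads `> min_reads`
#'   are kept (default 5000, i.e. a 5,000-read sample is removed and a
#'   5,001-read sample retained).
#' @return The filtered count matrix.  Removed samples are reported via
#'   `message()`; an empty result triggers a warning, not an error.
#' @export
filter_low_depth <- function(counts, min_reads = 5000) {
  .check_count_matrix(counts)
  depth <- rowSums(counts)
  keep <- depth > min_reads
  if (any(!keep)) {
    message("filter_low_depth: removing ", sum(!keep), " sample(s) at <= ",
            min_reads, " reads: ",
            paste(rownames(counts)[!keep], collapse = ", "))
  }
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no samples exceed the minimum read depth; ",
            "returning an empty table")
  }
  out
}

#' Pseudocounted relative abundances
#'
#' Adds a pseudocount to every cell (avoiding logs of zero downstream)
#' and normalises each sample to proportions:
#' `(count + pseudocount) / sum(count + pseudocount)`.
#'
#' @inheritParams filter_low_depth
#' @param pseudocount Value added to every count before normalisation
#'   (default 1).
#' @return Matrix of relative abundances; every row sums to 1.
#' @export
to_relative_with_pseudocount <- function(counts, pseudocount = 1) {
  .check_count_matrix(counts)
  if (ncol(counts) == 0L) stop("count table has no SV columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  x <- counts + pseudocount
  sweep(x, 1L, rowSums(x), "/")
}

#' Scale relative abundances to absolute units by total 16S qPCR
#'
#' Multiplies each sample's relative SV abundances by that sample's total
#' 16S concentration, yielding per-SV abundances in qPCR units.  Row sums
#' of the result equal the qPCR totals.
#'
#' @param rel Matrix of relative abundances (rows sum to 1), samples x SVs.
#' @param qpcr Named numeric vector of total 16S concentrations (arbitrary
#'   calibrated units), with names covering every sample in `rel`.
#'   Negative values (instrument artifacts) are clamped to 0 with a
#'   warning.
#' @return Matrix of absolute abundances, same shape as `rel`.
#' @export
absolute_abundance <- function(rel, qpcr) {
  .check_count_matrix(rel, "rel")
  if (is.null(names(qpcr))) stop("'qpcr' must be a named vector")
  missing <- setdiff(rownames(rel), names(qpcr))
  if (length(missing) > 0L) {
    stop("no qPCR entry for sample(s): ", paste(missing, collapse = ", "))
  }
  q <- qpcr[rownames(rel)]
  if (any(q < 0)) {
    warning("clamping ", sum(q < 0), " negative qPCR value(s) to 0")
    q[q < 0] <- 0
  }
  rel * q
}

#' SVs detected in enough samples
#'
#' Detection is defined on raw read counts (a non-zero count in a sample),
#' never on pseudocounted values; an SV is retained if it is detected in
#' strictly more than `min_samples` samples.  Downstream curve fitting is
#' restricted to these SVs.
#'
#' @inheritParams filter_low_depth
#' @param min_samples Presence cutoff; SVs detected in `> min_samples`
#'   samples are kept (default 5).
#' @return Character vector of retained SV ids.
#' @export
detection_filter <- function(counts, min_samples = 5) {
  .check_count_matrix(counts)
  presence <- colSums(counts > 0)
  colnames(counts)[presence > min_samples]
}

#' Fractions of inoculum taxa captured by droplet culture
#'
#' Given, per taxonomic level, the number of taxa in the inoculating
#' sample, the number of those also detected in droplet culture, and the
#' number of those inferred to have grown in droplets, computes the
#' detected-in-droplets and grew-in-droplets fractions of the inoculum.
#'
#' @param counts Data frame with columns `level`, `n_inoculum`,
#'   `n_inoculum_detected` and `n_inoculum_grew` (see
#'   `system.file("extdata", "capture_counts_mgam_timeseries.tsv",
#'   package = "dropcult")` for the layout and a worked dataset).
#' @param digits Rounding applied to the fractions (default 2, matching
#'   two-decimal reporting).
#' @return The input with `fraction_detected` and `fraction_grew` columns
#'   appended.
#' @export
capture_fractions <- function(counts, digits = 2) {
  need <- c("level", "n_inoculum", "n_inoculum_detected", "n_inoculum_grew")
  if (!all(need %in% names(counts))) {
    stop("'counts' must have columns: ", paste(need, collapse = ", "))
  }
  if (any(counts$n_inoculum <= 0)) stop("'n_inoculum' must be positive")
  counts$fraction_detected <-
    round(counts$n_inoculum_detected / counts$n_inoculum, digits)
  counts$fraction_grew <-
    round(counts$n_inoculum_grew / counts$n_inoculum, digits)
  counts
}
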