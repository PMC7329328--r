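# Growth/no-growth calls: reference well-plate thresholding, endpoint
# preprocessing against no-carbon controls, ROC/Youden threshold
# calibration, and confusion-matrix metrics.

#' Boolean growth calls from reference well-plate OD endpoints
#'
#' Normalises each isolate's OD endpoints to its own maximum across
#' carbon sources and calls growth where the normalised value exceeds
#' 20% of that maximum (strictly).  This is the conventional reference
#' against which a droplet assay is calibrated.
#'
#' @param od Numeric matrix of OD600 endpoints, isolates x carbons.
#' @param threshold Fraction of the per-isolate maximum above which
#'   growth is called (default 0.20).
#' @return Logical matrix of the same shape.  An all-zero isolate row
#'   yields all-`FALSE` with a warning.
#' @export
plate_growth_reference <- function(od, threshold = 0.20) {
  if (!is.matrix(od) || !is.numeric(od)) {
    stop("'od' must be a numeric matrix (isolates x carbons)")
  }
  if (any(od < 0)) stop("OD values must be non-negative")
  mx <- apply(od, 1L, max)
  if (any(mx == 0)) {
    warning("isolate(s) with no growth on any carbon: ",
            paste(rownames(od)[mx == 0], collapse = ", "),
            "; all calls set to FALSE")
  }
  out <- sweep(od, 1L, threshold * mx, ">")
  out[mx == 0, ] <- FALSE
  out
}

#' Preprocess endpoint droplet assays against no-carbon controls
#'
#' Implements the endpoint preprocessing chain for a matched set of
#' droplet cultures (one donor/session): (1) any sample whose qPCR total
#' falls below the mean of the no-carbon controls is treated as showing
#' no overall growth and its qPCR total is set to 0; (2) pseudocounted
#' relative abundances are scaled to absolute abundances; (3) per-SV
#' medians are taken across replicates within each condition; (4) the
#' matched no-carbon medians are subtracted; (5) negative values are
#' floored at 0.  Split multi-donor or multi-session data and call once
#' per matched set.
#'
#' @param counts Integer matrix of read counts, samples x SVs.
#' @param metadata Data frame with columns `sample`, `condition`,
#'   `replicate` covering every row of `counts`.
#' @param qpcr Named numeric vector of total 16S concentrations.
#' @param no_carbon Condition label of the no-carbon control (default
#'   `"none"`); must be present with at least one replicate.
#' @param pseudocount Pseudocount for the relative-abundance step
#'   (default 1).
#' @return Numeric matrix of control-subtracted growth values, SVs x
#'   conditions (the no-carbon column is consumed by the subtraction and
#'   not returned).
#' @export
preprocess_endpoint <- function(counts, metadata, qpcr,
                                no_carbon = "none", pseudocount = 1) {
  .check_count_matrix(counts)
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(metadata))) {
    stop("'metadata' must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(rownames(counts) %in% metadata$sample)) {
    stop("metadata is missing sample(s): ",
         paste(setdiff(rownames(counts), metadata$sample), collapse = ", "))
  }
  meta <- metadata[match(rownames(counts), metadata$sample), ]
  if (!no_carbon %in% meta$condition) {
    stop("no-carbon control condition \"", no_carbon,
         "\" not present in the data")
  }

  # (1) zero out samples whose overall growth is below the no-carbon mean
  q <- qpcr[rownames(counts)]
  if (any(is.na(q))) {
    stop("no qPCR entry for sample(s): ",
         paste(rownames(counts)[is.na(q)], collapse = ", "))
  }
  baseline <- mean(q[meta$condition == no_carbon])
  q[q < baseline] <- 0

  # (2) absolute abundances
  rel <- to_relative_with_pseudocount(counts, pseudocount)
  abs_tab <- absolute_abundance(rel, q)

  # (3) per-condition, per-SV medians across replicates
  conditions <- unique(meta$condition)
  med <- vapply(conditions, function(cond) {
    apply(abs_tab[meta$condition == cond, , drop = FALSE], 2L,
          stats::median)
  }, numeric(ncol(counts)))
  colnames(med) <- conditions

  # (4, 5) subtract matched no-carbon medians, floor at 0
  out <- med[, setdiff(conditions, no_carbon), drop = FALSE] -
    med[, no_carbon]
  out[out < 0] <- 0
  out
}

#' Calibrate a growth threshold by ROC analysis and Youden's J
#'
#' Sweeps every decision threshold over the scores (midpoints between
#' consecutive sorted unique values, plus sentinels below and above all
#' scores), classifying `score >= threshold` as growth, and returns the
#' threshold maximising Youden's J = TPR - FPR against the reference
#' labels.  Ties in J are broken toward the smallest threshold (the most
#' sensitive of the equally good cut-offs), so the result is
#' deterministic.
#'
#' @param scores Numeric growth scores, one per (SV, carbon) assay.
#' @param labels Logical reference calls, same length; both classes must
#'   be present.
#' @return An object of class `"growth_threshold"`: a list with
#'   `threshold`, `j_statistic`, `tpr`, `fpr`, and `roc_points` (a data
#'   frame of `threshold`, `tpr`, `fpr` sorted by threshold).
#' @export
roc_youden <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have the same length")
  }
  if (any(!is.finite(scores))) stop("'scores' must be finite")
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("'labels' must be TRUE/FALSE")
  if (!any(labels) || all(labels)) {
    stop("ROC is undefined: reference labels contain a single class")
  }
  s <- sort(unique(scores))
  gap <- if (length(s) > 1L) min(diff(s)) else 1
  cand <- c(s[1L] - gap,
            if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
            s[length(s)] + gap)
  npos <- sum(labels)
  nneg <- sum(!labels)
  tpr <- vapply(cand, function(th) sum(scores >= th & labels) / npos,
                numeric(1L))
  fpr <- vapply(cand, function(th) sum(scores >= th & !labels) / nneg,
                numeric(1L))
  j <- tpr - fpr
  best <- which(j >= max(j) - 1e-12)[1L]  # candidates sorted ascending
  structure(
    list(threshold = cand[best], j_statistic = j[best],
         tpr = tpr[best], fpr = fpr[best],
         roc_points = data.frame(threshold = cand, tpr = tpr, fpr = fpr)),
    class = "growth_threshold")
}

#' @export
print.growth_threshold <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Calibrated growth threshold %s (Youden's J = %s; TPR %s, FPR %s)\n",
    format(x$threshold, digits = digits),
    format(x$j_statistic, digits = digits),
    format(x$tpr, digits = digits), format(x$fpr, digits = digits)))
  invisible(x)
}

#' Apply a growth threshold to a growth matrix
#'
#' Calls growth wherever the value is at or above the threshold (a
#' closed inequality: a total growth of exactly 1.48 ln-units meets the
#' default kinetics limit of detection).
#'
#' @param x Numeric matrix (or vector) of growth values.
#' @param threshold Decision threshold on the same scale as `x`.  The
#'   kinetics-mode limit of detection is 1.48 ln-units (~2.14
#'   doublings); endpoint-mode thresholds must be calibrated with
#'   [roc_youden()] and have no default.
#' @return Logical matrix/vector of the same shape.
#' @export
classify_growth <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold)) {
    stop("'threshold' must be a single finite number")
  }
  x >= threshold
}

#' Confusion-matrix metrics of predicted vs reference growth calls
#'
#' @param predicted,reference Logical matrices (or vectors) of identical
#'   shape.
#' @return A list with `accuracy`, `sensitivity` (TP / (TP + FN)),
#'   `specificity` (TN / (TN + FP)), `false_discovery_rate`
#'   (FP / (TP + FP)), and the raw counts `tp`, `fp`, `tn`, `fn`.
#'   Metrics with a zero denominator are `NA` (undefined), never 0.
#' @export
confusion_metrics <- function(predicted, reference) {
  if (length(predicted) != length(reference) ||
      !identical(dim(predicted), dim(reference))) {
    stop("'predicted' and 'reference' must have identical shape")
  }
  p <- as.logical(predicted)
  r <- as.logical(reference)
  if (anyNA(p) || anyNA(r)) stop("growth calls must be TRUE/FALSE")
  tp <- sum(p & r); fp <- sum(p & !r)
  tn <- sum(!p & !r); fn <- sum(!p & r)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = safe_div(tp + tn, tp + fp + tn + fn),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       false_discovery_rate = safe_div(fp, tp + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}
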