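# Ecology statistics on SV x carbon growth matrices: primary degraders,
# specialist/generalist structure, permutation tests, prebiotic
# combination coverage and enrichment, profile clustering, Mantel tests.

# Polysaccharide columns of a growth matrix: everything except the
# viability (glucose) and no-carbon controls unless given explicitly.
.poly_cols <- function(mat, polysaccharides = NULL) {
  if (is.null(polysaccharides)) {
    polysaccharides <- setdiff(colnames(mat), c("glucose", "none"))
  }
  if (length(polysaccharides) == 0L ||
      !all(polysaccharides %in% colnames(mat))) {
    stop("no usable polysaccharide columns; flag them explicitly via ",
         "'polysaccharides'")
  }
  polysaccharides
}

.check_growth_matrix <- function(mat) {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("growth matrix must be a matrix with SV rownames and carbon ",
         "colnames")
  }
  if (!is.logical(mat)) {
    stop("boolean growth calls expected; threshold continuous values ",
         "with classify_growth() first")
  }
  invisible(mat)
}

#' Primary degraders of a growth matrix
#'
#' SVs that grew on at least one polysaccharide as the sole carbon
#' source.  Glucose (the viability control) and the no-carbon condition
#' never count.
#'
#' @param mat Logical growth matrix, SVs x carbons.
#' @param polysaccharides Columns to treat as polysaccharides; defaults
#'   to every column except `"glucose"` and `"none"`.
#' @return Character vector of primary-degrader SV ids.
#' @export
primary_degraders <- function(mat, polysaccharides = NULL) {
  .check_growth_matrix(mat)
  polys <- .poly_cols(mat, polysaccharides)
  rownames(mat)[rowSums(mat[, polys, drop = FALSE]) >= 1L]
}

#' Specialist/generalist lifestyle per SV
#'
#' Counts each SV's polysaccharide utilizations: exactly one makes it a
#' specialist, two or more a generalist, none a nondegrader.  Specialists
#' and generalists together are exactly the primary degraders.
#'
#' @inheritParams primary_degraders
#' @return Named factor with levels `nondegrader`, `specialist`,
#'   `generalist`.
#' @export
classify_lifestyle <- function(mat, polysaccharides = NULL) {
  .check_growth_matrix(mat)
  polys <- .poly_cols(mat, polysaccharides)
  k <- rowSums(mat[, polys, drop = FALSE])
  out <- factor(ifelse(k == 0, "nondegrader",
                       ifelse(k == 1, "specialist", "generalist")),
                levels = c("nondegrader", "specialist", "generalist"))
  names(out) <- rownames(mat)
  out
}

#' Normalise primary-degrader statistics by glucose consumers
#'
#' Divides a per-donor primary-degrader statistic (richness count or
#' summed stool abundance) by the matching glucose-consumer statistic to
#' control for differences in overall sample viability.
#'
#' @param pd Numeric vector of per-donor primary-degrader statistics.
#' @param gc Matching vector of glucose-consumer statistics.
#' @return `pd / gc`, with `NA` (and a warning) wherever `gc` is 0.
#' @export
normalize_by_glucose <- function(pd, gc) {
  if (length(pd) != length(gc)) stop("'pd' and 'gc' must match in length")
  if (any(gc < 0) || any(pd < 0)) stop("statistics must be non-negative")
  out <- pd / gc
  if (any(gc == 0)) {
    warning("glucose-consumer statistic is 0 for ", sum(gc == 0),
            " donor(s); ratio undefined (NA)")
    out[gc == 0] <- NA_real_
  }
  out
}

#' Permutation test of phylum-by-lifestyle enrichment
#'
#' Tests, for every combination of phylum and lifestyle (specialist or
#' generalist), whether the observed number of member SVs exceeds chance.
#' The null is generated by shuffling the SV-to-phylum assignment while
#' keeping each SV's utilization profile (hence its lifestyle) intact;
#' the one-sided p-value is the add-one-corrected fraction of
#' permutations in which the shuffled count reaches or exceeds the
#' observed count.
#'
#' @inheritParams primary_degraders
#' @param taxonomy Named character vector of phylum labels covering every
#'   SV row of `mat`.
#' @param n_perm Number of permutations (default 10000; fewer than 100
#'   draws a warning).
#' @param seed Optional integer seed.
#' @return A data frame with one row per (phylum, lifestyle): `observed`,
#'   `exceed_count`, `n_perm`, `p_value`, `significant` (p < 0.05).
#' @export
phylum_lifestyle_permutation <- function(mat, taxonomy,
                                         polysaccharides = NULL,
                                         n_perm = 10000, seed = NULL) {
  .check_growth_matrix(mat)
  if (n_perm < 100) warning("fewer than 100 permutations; p-values crude")
  missing <- setdiff(rownames(mat), names(taxonomy))
  if (length(missing) > 0L) {
    stop("taxonomy missing for SV(s): ", paste(missing, collapse = ", "))
  }
  phylum <- factor(taxonomy[rownames(mat)])
  lifestyle <- classify_lifestyle(mat, polysaccharides)
  degrader <- lifestyle != "nondegrader"
  if (nlevels(droplevels(phylum[degrader])) < 2L) {
    warning("fewer than 2 phyla among degraders; nothing to shuffle ",
            "(all p-values 1)")
  }

  lifestyles <- c("specialist", "generalist")
  nph <- nlevels(phylum)
  nls <- length(lifestyles)
  ls_idx <- match(as.character(lifestyle), lifestyles)  # NA = nondegrader
  ph_idx <- as.integer(phylum)
  ncell <- nph * nls
  cell_of <- function(ph) {
    idx <- ph + nph * (ls_idx - 1L)
    tabulate(idx[!is.na(idx)], nbins = ncell)
  }
  observed <- cell_of(ph_idx)
  exceed <- integer(ncell)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      exceed <- exceed + (cell_of(sample(ph_idx)) >= observed)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  out <- data.frame(
    phylum = rep(levels(phylum), times = nls),
    lifestyle = rep(lifestyles, each = nph),
    observed = observed, exceed_count = exceed, n_perm = n_perm,
    p_value = p, significant = p < 0.05
  )
  out[order(out$phylum, out$lifestyle), ]
}

#' Coverage of primary degraders by prebiotic combinations
#'
#' For every size-`k` subset of the polysaccharides, the fraction of
#' primary degraders that grow on at least one member of the subset --
#' the fraction of the culturable degrading community a `k`-prebiotic
#' cocktail would stimulate.
#'
#' @inheritParams primary_degraders
#' @param k Cocktail size, between 1 and the number of polysaccharides.
#' @return A data frame of `combo` (members joined by `"+"`) and
#'   `coverage`, sorted by decreasing coverage (ties by combo name);
#'   the best combination is first.
#' @export
combo_coverage <- function(mat, k, polysaccharides = NULL) {
  .check_growth_matrix(mat)
  polys <- .poly_cols(mat, polysaccharides)
  if (k < 1 || k > length(polys)) {
    stop("'k' must be between 1 and the number of polysaccharides (",
         length(polys), ")")
  }
  deg <- primary_degraders(mat, polys)
  sub <- mat[deg, polys, drop = FALSE]
  combos <- utils::combn(polys, k, simplify = FALSE)
  cov <- vapply(combos, function(cc) {
    if (length(deg) == 0L) return(NA_real_)
    mean(rowSums(sub[, cc, drop = FALSE]) >= 1L)
  }, numeric(1L))
  nm <- vapply(combos, paste, character(1L), collapse = "+")
  out <- data.frame(combo = nm, coverage = cov)
  out[order(-out$coverage, out$combo), ]
}

#' Permutation test of utilization-pattern enrichment
#'
#' Asks which exact carbon-utilization patterns (rows of the boolean
#' matrix, e.g. "inulin+xylan") occur more or less often than chance.
#' The null preserves each carbon's prevalence by shuffling every column
#' independently across SVs; each observed pattern's count is compared
#' against its permuted counts in both tails (add-one corrected).
#'
#' @inheritParams primary_degraders
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A data frame with one row per pattern observed in the data:
#'   `pattern`, `n_carbons`, `observed`, `p_over`, `p_under`,
#'   `enriched` / `depleted` flags at p < 0.05.  With a single carbon
#'   there are no combinations and the result is empty.
#' @export
combo_enrichment <- function(mat, polysaccharides = NULL, n_perm = 10000,
                             seed = NULL) {
  .check_growth_matrix(mat)
  polys <- .poly_cols(mat, polysaccharides)
  if (length(polys) < 2L) {
    return(data.frame(pattern = character(), n_carbons = integer(),
                      observed = integer(), p_over = numeric(),
                      p_under = numeric(), enriched = logical(),
                      depleted = logical()))
  }
  sub <- mat[, polys, drop = FALSE]
  pattern_key <- function(m) {
    apply(m, 1L, function(r) {
      if (!any(r)) "(none)" else paste(polys[r], collapse = "+")
    })
  }
  obs_keys <- pattern_key(sub)
  patterns <- sort(unique(obs_keys))
  observed <- as.integer(table(factor(obs_keys, levels = patterns)))
  over <- integer(length(patterns))
  under <- integer(length(patterns))
  n_sv <- nrow(sub)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- apply(sub, 2L, sample)
      cnt <- as.integer(table(factor(pattern_key(perm),
                                     levels = patterns)))
      over <- over + (cnt >= observed)
      under <- under + (cnt <= observed)
    }
  })
  p_over <- (over + 1) / (n_perm + 1)
  p_under <- (under + 1) / (n_perm + 1)
  data.frame(
    pattern = patterns,
    n_carbons = vapply(strsplit(patterns, "+", fixed = TRUE), function(x) {
      if (identical(x, "(none)")) 0L else length(x)
    }, integer(1L)),
    observed = observed, p_over = p_over, p_under = p_under,
    enriched = p_over < 0.05, depleted = p_under < 0.05
  )
}

#' Hierarchical clustering of growth profiles
#'
#' Agglomerative clustering of SVs on the Euclidean distance between
#' their (continuous) growth profiles, with a default two-group cut --
#' the split that typically separates single-carbohydrate from
#' multi-carbohydrate growers.
#'
#' @param mat Numeric matrix of growth values, SVs x carbons.
#' @param k Number of clusters to cut (default 2); ignored if
#'   `cut_height` is given.
#' @param cut_height Optional dendrogram height at which to cut instead
#'   of `k` (the cut is a judgement call; expose it when the two-group
#'   default is not appropriate).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return A list with `tree` (an `hclust` object) and `cluster` (named
#'   integer assignment).  Duplicate profiles are at distance 0 and land
#'   in the same cluster; ties are resolved deterministically by row
#'   order.
#' @export
cluster_profiles <- function(mat, k = 2, cut_height = NULL,
                             linkage = "average") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("'mat' must be a numeric matrix (SVs x carbons)")
  }
  if (nrow(mat) < 2L) stop("at least 2 SVs are required to cluster")
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = linkage)
  cluster <- if (is.null(cut_height)) {
    stats::cutree(tree, k = k)
  } else {
    stats::cutree(tree, h = cut_height)
  }
  list(tree = tree, cluster = cluster)
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation `r_M` between the off-diagonal entries of two
#' distance matrices over the same objects, with significance from
#' jointly permuting the rows and columns of the second matrix.  The
#' p-value is one-sided (greater) with add-one correction.  Taxonomic
#' structure at a given rank can be encoded as a 0/1 same-taxon distance
#' matrix.
#'
#' @param d1,d2 Square symmetric distance matrices (or `dist` objects)
#'   over the same objects in the same order, size >= 3.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return An object of class `"mantel_result"`: a list with `r_m`,
#'   `p_value`, `n_perm`, `exceed_count`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  as_dmat <- function(d, what) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8)) {
      stop("'", what, "' must be a square symmetric matrix")
    }
    m
  }
  m1 <- as_dmat(d1, "d1")
  m2 <- as_dmat(d2, "d2")
  n <- nrow(m1)
  if (nrow(m2) != n) stop("'d1' and 'd2' must have the same size")
  if (n < 3L) stop("Mantel test requires at least 3 objects")
  lower <- lower.tri(m1)
  v1 <- m1[lower]
  r_obs <- stats::cor(v1, m2[lower])
  exceed <- 0L
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample(n)
      r_perm <- stats::cor(v1, m2[idx, idx][lower])
      if (r_perm >= r_obs) exceed <- exceed + 1L
    }
  })
  structure(
    list(r_m = r_obs, p_value = (exceed + 1) / (n_perm + 1),
         n_perm = n_perm, exceed_count = exceed),
    class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, digits = 4, ...) {
  cat(sprintf("Mantel test: r_M = %s, p = %s (%d permutations)\n",
              format(x$r_m, digits = digits),
              format(x$p_value, digits = digits), x$n_perm))
  invisible(x)
}
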