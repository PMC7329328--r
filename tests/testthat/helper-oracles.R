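# Independent oracles and fixture builders shared across tests.

# Brute-force Youden maximisation: try every candidate threshold (all
# score values and midpoints, plus outer sentinels) by direct counting.
brute_force_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  gap <- if (length(s) > 1L) min(diff(s)) else 1
  cand <- sort(c(s, s - gap / 2, s[length(s)] + gap))
  best_j <- -Inf
  best_thr <- NA_real_
  for (th in cand) {
    pred <- scores >= th
    tpr <- sum(pred & labels) / sum(labels)
    fpr <- sum(pred & !labels) / sum(!labels)
    if (tpr - fpr > best_j + 1e-12) {
      best_j <- tpr - fpr
      best_thr <- th
    }
  }
  list(j = best_j, threshold = best_thr)
}

# Exact phylum-by-lifestyle enrichment p-values by enumerating every
# distinct assignment of phylum labels to SVs (small n only).
enumerate_phylum_p <- function(phylum, lifestyle) {
  phylum <- factor(phylum)
  lifestyles <- c("specialist", "generalist")
  nph <- nlevels(phylum)
  counts_of <- function(ph) {
    sapply(lifestyles, function(l) {
      sapply(levels(phylum), function(p) sum(ph == p & lifestyle == l))
    })  # nph x 2
  }
  obs <- counts_of(phylum)
  perms <- combinat_perms(as.character(phylum))
  geq <- matrix(0, nph, length(lifestyles),
                dimnames = list(levels(phylum), lifestyles))
  for (i in seq_len(nrow(perms))) {
    geq <- geq + (counts_of(factor(perms[i, ], levels = levels(phylum)))
                  >= obs)
  }
  geq / nrow(perms)
}

# All distinct permutations of a label vector (multiset permutations),
# by recursion; fine for length <= 8.
combinat_perms <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- NULL
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    sub <- combinat_perms(rest)
    out <- rbind(out, cbind(v, sub, deparse.level = 0))
  }
  out
}

# Build a community_spec by hand with fully specified fields, bypassing
# the random draws, so tests control the ground truth exactly.
manual_spec <- function(A, mu, lam, A0, growing = mu > 0,
                        fractions = NULL, taxonomy = NULL,
                        truth = NULL, carbons = c("inulin", "xylan")) {
  n <- length(A)
  sv_ids <- sprintf("SV%03d", seq_len(n))
  params <- cbind(A = A, mu = mu, lam = lam, A0 = A0)
  rownames(params) <- sv_ids
  if (is.null(fractions)) {
    fractions <- exp(A0) / sum(exp(A0))
  }
  if (is.null(taxonomy)) taxonomy <- rep("Firmicutes", n)
  if (is.null(truth)) {
    truth <- matrix(FALSE, n, length(carbons),
                    dimnames = list(sv_ids, carbons))
  } else {
    dimnames(truth) <- list(sv_ids, carbons)
  }
  structure(
    list(sv_ids = sv_ids, growth_params = params, growing = growing,
         initial_fractions = stats::setNames(fractions, sv_ids),
         taxonomy = stats::setNames(taxonomy, sv_ids),
         utilization_truth = truth, carbons = carbons,
         total_inoculum = sum(exp(A0))),
    class = "community_spec")
}

# The 29-point destructive sampling design: hourly for the first day,
# then daily out to 127 h.
design_times <- function() c(0:24, 48, 72, 96, 127)

# Random boolean growth matrix with named rows/columns.
random_growth_matrix <- function(n_sv, carbons, p = 0.4) {
  m <- matrix(runif(n_sv * length(carbons)) < p, n_sv,
              dimnames = list(sprintf("SV%03d", seq_len(n_sv)), carbons))
  m
}
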