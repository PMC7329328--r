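# Ecology statistics on growth matrices.

toy_matrix <- function() {
  m <- rbind(
    SV1 = c(none = FALSE, glucose = TRUE, inulin = FALSE, xylan = FALSE),
    SV2 = c(FALSE, TRUE, TRUE, FALSE),
    SV3 = c(FALSE, TRUE, TRUE, TRUE),
    SV4 = c(FALSE, FALSE, FALSE, TRUE),
    SV5 = c(FALSE, TRUE, FALSE, FALSE))
  colnames(m) <- c("none", "glucose", "inulin", "xylan")
  m
}

test_that("primary degraders need growth on a polysaccharide", {
  m <- toy_matrix()
  expect_identical(primary_degraders(m), c("SV2", "SV3", "SV4"))
  # glucose-only growers are excluded; an all-false matrix gives none
  empty <- m & FALSE
  expect_identical(primary_degraders(empty), character(0))
  expect_error(primary_degraders(m[, "glucose", drop = FALSE] > 0),
               "polysaccharide")
})

test_that("lifestyle classification partitions the degraders", {
  m <- toy_matrix()
  ls <- classify_lifestyle(m)
  expect_identical(as.character(ls[c("SV2", "SV3", "SV4", "SV5")]),
                   c("specialist", "generalist", "specialist",
                     "nondegrader"))
  set.seed(51)
  for (i in 1:10) {
    mm <- random_growth_matrix(30, c("a", "b", "c"))
    lsm <- classify_lifestyle(mm)
    expect_identical(sum(lsm != "nondegrader"),
                     length(primary_degraders(mm)))
  }
})

test_that("glucose normalisation is a guarded elementwise ratio", {
  expect_equal(normalize_by_glucose(12, 24), 0.5)
  expect_equal(normalize_by_glucose(7, 7), 1)
  expect_equal(normalize_by_glucose(c(2, 4), c(4, 4)) * 2,
               normalize_by_glucose(c(2, 4) * 2, c(4, 4)))
  expect_warning(out <- normalize_by_glucose(c(1, 1), c(2, 0)),
                 "undefined")
  expect_equal(out, c(0.5, NA))
})

test_that("phylum-lifestyle permutation p-values match exact enumeration", {
  # 3 specialists in phylum X, 3 generalists in phylum Y: exact
  # enumeration over all 20 distinct label assignments
  m <- rbind(SV1 = c(TRUE, FALSE), SV2 = c(TRUE, FALSE),
             SV3 = c(FALSE, TRUE),
             SV4 = c(TRUE, TRUE), SV5 = c(TRUE, TRUE),
             SV6 = c(TRUE, TRUE))
  colnames(m) <- c("inulin", "xylan")
  tax <- setNames(c("X", "X", "X", "Y", "Y", "Y"), rownames(m))
  exact <- enumerate_phylum_p(tax[rownames(m)],
                              as.character(classify_lifestyle(m)))
  expect_equal(exact["X", "specialist"], 1 / 20)
  got <- phylum_lifestyle_permutation(m, tax, n_perm = 20000, seed = 61)
  for (i in seq_len(nrow(got))) {
    expect_lt(abs(got$p_value[i] -
                    exact[got$phylum[i], got$lifestyle[i]]), 0.012)
  }
  expect_true(all(got$p_value >= 1 / 20001 & got$p_value <= 1))
})

test_that("a single phylum leaves nothing to shuffle", {
  m <- toy_matrix()
  tax <- setNames(rep("Firmicutes", 5), rownames(m))
  expect_warning(res <- phylum_lifestyle_permutation(m, tax,
                                                     n_perm = 200,
                                                     seed = 1),
                 "fewer than 2 phyla")
  expect_true(all(res$p_value == 1))
})

test_that("permutation results are seed-reproducible", {
  m <- random_growth_matrix(20, c("a", "b", "c"))
  tax <- setNames(sample(c("P1", "P2"), 20, replace = TRUE), rownames(m))
  r1 <- phylum_lifestyle_permutation(m, tax, n_perm = 500, seed = 7)
  r2 <- phylum_lifestyle_permutation(m, tax, n_perm = 500, seed = 7)
  expect_identical(r1, r2)
})

test_that("combination coverage counts set unions over degraders", {
  m <- toy_matrix()
  # all carbons cover every degrader by definition
  all_k <- combo_coverage(m, k = 2)
  expect_equal(all_k$coverage[all_k$combo == "inulin+xylan"], 1)
  # k = 1 equals each carbon's prevalence among the 3 degraders
  k1 <- combo_coverage(m, k = 1)
  expect_equal(k1$coverage[k1$combo == "inulin"], 2 / 3)
  expect_equal(k1$coverage[k1$combo == "xylan"], 2 / 3)
  expect_error(combo_coverage(m, k = 5), "between")
})

test_that("combination coverage matches a brute-force union oracle", {
  set.seed(52)
  m <- random_growth_matrix(25, c("a", "b", "c", "d"), p = 0.3)
  deg <- primary_degraders(m)
  for (k in 1:3) {
    got <- combo_coverage(m, k)
    for (i in seq_len(nrow(got))) {
      members <- strsplit(got$combo[i], "+", fixed = TRUE)[[1]]
      want <- mean(vapply(deg, function(sv) any(m[sv, members]),
                          logical(1)))
      expect_equal(got$coverage[i], want)
    }
    # monotone: the best (k+1)-cocktail covers at least the best k
    if (k < 3) expect_gte(max(combo_coverage(m, k + 1)$coverage),
                          max(got$coverage))
  }
})

test_that("pattern enrichment flags constructed nesting, not noise", {
  # perfectly nested: every xylan grower also grows on inulin, while
  # both carbons keep intermediate prevalence so the null has room
  m <- rbind(matrix(rep(c(TRUE, TRUE), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(TRUE, FALSE), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(FALSE, FALSE), 10), ncol = 2, byrow = TRUE))
  rownames(m) <- sprintf("SV%03d", seq_len(nrow(m)))
  colnames(m) <- c("inulin", "xylan")
  res <- combo_enrichment(m, n_perm = 2000, seed = 71)
  expect_true(res$enriched[res$pattern == "inulin+xylan"])
  expect_true(all(res$p_over >= 1 / 2001 & res$p_over <= 1))
  expect_true(all(res$p_under >= 1 / 2001 & res$p_under <= 1))
  # a single carbon admits no combinations
  single <- combo_enrichment(m[, "inulin", drop = FALSE],
                             polysaccharides = "inulin")
  expect_equal(nrow(single), 0)
})

test_that("profile clustering separates planted blocks", {
  set.seed(53)
  block1 <- matrix(rnorm(20 * 3, mean = c(5, 0, 0)), 20, 3, byrow = TRUE)
  block2 <- matrix(rnorm(15 * 3, mean = c(0, 5, 5)), 15, 3, byrow = TRUE)
  m <- rbind(block1, block2)
  rownames(m) <- sprintf("SV%03d", seq_len(nrow(m)))
  res <- cluster_profiles(m, k = 2)
  planted <- rep(1:2, c(20, 15))
  tab <- table(res$cluster, planted)
  expect_equal(sum(apply(tab, 2, max)), 35)  # perfect recovery up to label swap
  # duplicate rows land together; k = n gives singletons
  dup <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  resd <- cluster_profiles(dup, k = 2)
  expect_equal(resd$cluster[["a"]], resd$cluster[["b"]])
  expect_equal(length(unique(cluster_profiles(dup, k = 3)$cluster)), 3)
})

test_that("mantel_test matches exhaustive enumeration on 4 objects", {
  set.seed(54)
  d1 <- as.matrix(dist(matrix(rnorm(8), 4)))
  d2 <- as.matrix(dist(matrix(rnorm(8), 4)))
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  r_obs <- cor(v1, d2[lower])
  perms <- combinat_perms(as.character(1:4))
  r_all <- apply(perms, 1, function(p) {
    idx <- as.integer(p)
    cor(v1, d2[idx, idx][lower])
  })
  exact_p <- mean(r_all >= r_obs)
  got <- mantel_test(d1, d2, n_perm = 9999, seed = 81)
  expect_equal(got$r_m, r_obs)
  expect_equal(got$p_value, exact_p, tolerance = 0.02)
})

test_that("mantel_test behaves at the identity and null extremes", {
  set.seed(55)
  d <- as.matrix(dist(matrix(rnorm(20), 10)))
  self <- mantel_test(d, d, n_perm = 999, seed = 82)
  expect_equal(self$r_m, 1)
  expect_equal(self$p_value, 1 / 1000)
  other <- as.matrix(dist(matrix(rnorm(20), 10)))
  null <- mantel_test(d, other, n_perm = 999, seed = 83)
  expect_lt(abs(null$r_m), 0.6)
  expect_gt(null$p_value, 0.01)
  expect_error(mantel_test(d[1:2, 1:2], d[1:2, 1:2]), "at least 3")
})

test_that("mantel_test agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(56)
  d1 <- dist(matrix(rnorm(30), 10))
  d2 <- dist(matrix(rnorm(30), 10))
  got <- mantel_test(d1, d2, n_perm = 999, seed = 84)
  ref <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(got$r_m, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(got$p_value - ref$signif), 0.05)
})
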