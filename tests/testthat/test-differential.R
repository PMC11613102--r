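test_that("log2 fold change has the 0.26 <-> 20% correspondence", {
  m <- matrix(c(rep(12, 3), rep(10, 3)), nrow = 1,
              dimnames = list("g1", paste0("S", 1:6)))
  groups <- rep(c("case", "control"), each = 3)
  sf <- tibble::tibble(sample_id = paste0("S", 1:6), size_factor = rep(1, 6))
  lfc <- log2_fold_change(m, groups, sf, pseudocount = 0)
  expect_equal(lfc$log2fc, log2(1.2), tolerance = 1e-12)
  expect_equal(round(lfc$log2fc, 2), 0.26)
  # equal means give 0
  m0 <- matrix(rep(7, 6), nrow = 1, dimnames = dimnames(m))
  expect_equal(log2_fold_change(m0, groups, sf)$log2fc, 0)
})

test_that("log2 fold change matches independent recomputation on random data", {
  set.seed(20)
  m <- matrix(rpois(50 * 10, 60) + 1, nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("S", 1:10)))
  groups <- rep(c("case", "control"), each = 5)
  sf <- size_factors(m)
  lfc <- log2_fold_change(m, groups, sf, pseudocount = 1)
  sc <- sweep(m, 2, sf$size_factor, "/")
  manual <- log2((rowMeans(sc[, 1:5]) + 1) / (rowMeans(sc[, 6:10]) + 1))
  expect_equal(lfc$log2fc, unname(manual))
})

test_that("swapping group labels negates the fold change", {
  set.seed(21)
  m <- matrix(rpois(30 * 8, 40) + 1, nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("S", 1:8)))
  g1 <- rep(c("case", "control"), each = 4)
  g2 <- rep(c("control", "case"), each = 4)
  sf <- size_factors(m)
  expect_equal(log2_fold_change(m, g1, sf)$log2fc,
               -log2_fold_change(m, g2, sf)$log2fc)
})

test_that("exact Wilcoxon matches full enumeration at small n", {
  # complete separation at n = (2,2): 6 assignments, two extreme
  res <- wilcoxon_empirical_p(c(1, 2), c(3, 4))
  expect_equal(unname(res["p_raw"]), 2 / 6, tolerance = 1e-12)
  expect_equal(unname(res["p_empirical"]), 1 / 6, tolerance = 1e-12)
  # random tie-free cases up to (4,4) against the enumeration oracle
  set.seed(22)
  for (i in 1:10) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- sample(seq(1, 40), n1); y <- sample(seq(41, 80) + 0.5, n2)
    z <- sample(c(x, y))
    x <- z[seq_len(n1)]; y <- z[-seq_len(n1)]
    expect_equal(unname(wilcoxon_empirical_p(x, y)["p_raw"]),
                 oracle_wilcoxon_exact(x, y), tolerance = 1e-9)
  }
})

test_that("identical groups and constant input behave as documented", {
  res <- wilcoxon_empirical_p(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(res["p_raw"]), 1)
  expect_equal(unname(res["p_empirical"]), 0.5)
  expect_message(res2 <- wilcoxon_empirical_p(c(2, 2), c(2, 2)), "degenerate")
  expect_equal(unname(res2["p_raw"]), 1)
})

test_that("raw Wilcoxon p-values are uniform under the null at n = 21 vs 48", {
  set.seed(23)
  p <- replicate(5000, {
    unname(wilcoxon_empirical_p(rnorm(21), rnorm(48))["p_raw"])
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # the halving rule doubles the null pass rate on the empirical scale:
  # p_empirical < 0.05 is p_raw < 0.1, so ~10% of null features pass
  rate <- mean(p / 2 < 0.05)
  expect_lt(abs(rate - 0.10), 0.02)
  expect_gt(rate, mean(p < 0.05))
})

test_that("BH q-values equal the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
})

test_that("BH q-values equal the exhaustive step-up oracle on small grids", {
  grid <- c(0.01, 0.2, 0.5, 0.8, 1)
  for (len in 1:4) {
    combos <- expand.grid(rep(list(grid), len))
    for (r in seq_len(nrow(combos))) {
      p <- as.numeric(combos[r, ])
      expect_equal(bh_fdr(p), oracle_bh(p))
    }
  }
  set.seed(24)
  for (i in 1:200) {
    p <- round(runif(sample(5:8, 1)), 2)
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("BH is permutation-equivariant", {
  set.seed(25)
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
})

test_that("differential calls use strict thresholds", {
  rec <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        log2fc = c(0.30, 0.26, -0.30, -0.27),
                        p_raw = c(0.02, 0.02, 0.02, 0.2),
                        p_empirical = c(0.01, 0.01, 0.01, 0.1),
                        q = c(0.02, 0.02, 0.02, 0.2))
  called <- call_differential(rec)
  expect_equal(called$direction, c("hyper", "ns", "hypo", "ns"))
  expect_equal(attr(called, "n_hyper"), 1)
  expect_equal(attr(called, "n_hypo"), 1)
})

test_that("planted differential features are recovered at the stated thresholds", {
  # 100 planted among 200 features (half hyper, half hypo in expectation)
  sim <- simulate_counts(hmc_sim_config(
    n_features = 200, n_case = 21, n_control = 48,
    frac_differential = 0.5, delta_log2fc = 1,
    size_factor_range = c(0.8, 1.25), seed = 26))
  d <- differential_test(sim$counts, sim$samples$group)
  called <- call_differential(d)
  truth_ids <- sim$truth$differential_feature_ids
  called_ids <- called$feature_id[called$direction != "ns"]
  expect_gte(mean(truth_ids %in% called_ids), 0.90)
  false_calls <- setdiff(called_ids, truth_ids)
  expect_lte(length(false_calls) / max(length(called_ids), 1), 0.10)
  # directions match the planted sign
  truth <- sim$truth$log2fc
  hyper_ids <- called$feature_id[called$direction == "hyper"]
  expect_true(all(truth$true_log2fc[truth$feature_id %in%
                                      intersect(hyper_ids, truth_ids)] > 0))
})

test_that("covariate screen keeps ~1% of null features and controls confounding", {
  set.seed(27)
  n <- 69
  status <- rep(c("case", "control"), c(21, 48))
  age <- rnorm(n, 60, 8)
  gender <- sample(c("male", "female"), n, TRUE)
  m <- matrix(rnorm(2000 * n), 2000, n,
              dimnames = list(paste0("g", 1:2000), paste0("S", 1:n)))
  scr <- covariate_screen(m, status, age, gender)
  rate <- mean(scr$keep)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 2000) + 0.005)
  # an age-driven feature with no residual effect is not retained
  age2 <- ifelse(status == "case", rnorm(n, 70, 3), rnorm(n, 55, 3))
  feat <- matrix(age2 + rnorm(n, 0, 1), 1, n,
                 dimnames = list("f", paste0("S", 1:n)))
  scr2 <- covariate_screen(feat, status, age2, gender)
  expect_false(scr2$keep[1] && !scr2$separation[1])
  # a perfectly separating feature is kept and flagged
  sep <- matrix(as.numeric(status == "case") + rnorm(n, 0, 1e-4), 1, n,
                dimnames = list("s", paste0("S", 1:n)))
  scr3 <- covariate_screen(sep, status, age, gender)
  expect_true(scr3$keep[1])
  expect_true(scr3$separation[1])
  expect_equal(scr3$p[1], 0)
})

test_that("hierarchical clustering merges duplicates first and recovers blocks", {
  set.seed(28)
  base <- matrix(rnorm(50 * 4), 50, 4)
  m <- cbind(base[, 1], base[, 1], base[, 2] + 5 * rnorm(50))
  colnames(m) <- c("A", "B", "C")
  rownames(m) <- paste0("g", 1:50)
  hc <- hierarchical_cluster(m)
  expect_equal(hc$hclust$height[1], 0, tolerance = 1e-12)
  # two planted blocks of two samples
  blk <- cbind(base[, 1], base[, 1] + 0.1 * rnorm(50),
               base[, 2], base[, 2] + 0.1 * rnorm(50))
  colnames(blk) <- c("A1", "A2", "B1", "B2")
  rownames(blk) <- paste0("g", 1:50)
  hc2 <- hierarchical_cluster(blk)
  k2 <- cutree(hc2$hclust, k = 2)
  expect_equal(k2[["A1"]], k2[["A2"]])
  expect_equal(k2[["B1"]], k2[["B2"]])
  expect_false(k2[["A1"]] == k2[["B1"]])
  # single sample: trivial tree
  hc1 <- hierarchical_cluster(m[, 1, drop = FALSE])
  expect_null(hc1$hclust)
  expect_equal(hc1$order, "A")
})
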