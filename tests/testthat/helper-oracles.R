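# Independent brute-force oracles used to check the package's
# implementations. These deliberately use the most direct definition of
# each quantity, not the package's code path.

# Feature x sample tibble (feature_id first column) -> rownamed matrix.
as_matrix_acc <- function(tbl) {
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl[[1]]
  m
}

# Step-up BH by literal definition: q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n1+n2, n1) group assignments (ties handled via midranks).
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  p
}

# AUC from the Mann-Whitney identity with midranks.
oracle_auc_mw <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fragment-midpoint counting by brute-force interval scan.
oracle_midpoint_count <- function(frags, catalog) {
  mid <- floor((frags$start + frags$end) / 2)
  vapply(seq_len(nrow(catalog)), function(g) {
    sum(frags$chrom == catalog$chrom[g] &
          mid >= catalog$start[g] & mid < catalog$end[g])
  }, numeric(1))
}

# Median-of-ratios size factors straight from the definition.
oracle_size_factors <- function(m) {
  pos <- apply(m > 0, 1, all)
  geo <- apply(m[pos, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) median(col / geo))
  sf / exp(mean(log(sf)))
}

# Pearson chi-square for a 2x2 table by the closed formula
# n (ad - bc)^2 / (r1 r2 c1 c2).
oracle_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Product-limit survival by hand at given event/censor times.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  tibble::tibble(time = ut, survival = out)
}
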