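# Per-feature differential hydroxymethylation between progression cases and
# controls: fold changes on size-factor-scaled counts, Wilcoxon rank-sum
# p-values with the empirical halving convention, BH FDR, threshold calls,
# a covariate-adjusted logistic screen and sample clustering.

#' Per-feature log2 fold change on scaled counts
#'
#' `log2((mean scaled case count + pc) / (mean scaled control count + pc))`,
#' case minus control orientation. Computed from size-factor-scaled raw
#' counts (not model coefficients), which makes the 0.26 threshold coincide
#' with a 20% fold change: `log2(1.2) = 0.263`.
#'
#' @param counts Count tibble or matrix (features x samples).
#' @param groups Character/factor per sample with levels `case`, `control`.
#' @param factors Optional [size_factors()] tibble; computed if `NULL`.
#' @param pseudocount Added to each group mean before the ratio (default 1).
#' @return Tibble `feature_id`, `log2fc`.
#' @export
log2_fold_change <- function(counts, groups, factors = NULL, pseudocount = 1) {
  m <- as_feature_matrix(counts)
  groups <- as.character(groups)
  stopifnot_config(length(groups) == ncol(m) &&
                     all(groups %in% c("case", "control")),
                   "`groups` must label every sample as case or control")
  if (is.null(factors)) factors <- size_factors(m, pseudocount = 1)
  sf <- setNames(factors$size_factor, factors$sample_id)[colnames(m)]
  scaled <- sweep(m, 2, sf, "/")
  mc <- rowMeans(scaled[, groups == "case", drop = FALSE])
  m0 <- rowMeans(scaled[, groups == "control", drop = FALSE])
  tibble(feature_id = rownames(m),
         log2fc = unname(log2((mc + pseudocount) / (m0 + pseudocount))))
}

#' Wilcoxon rank-sum test with the empirical halving convention
#'
#' Two-sided rank-sum p-value (exact null enumeration when
#' `n1 * n2 <= 400` and the pooled values are tie-free, otherwise the
#' normal approximation with tie and continuity correction), together with
#' the "empirical" p-value defined as the two-sided p divided by 2. The
#' halving convention is reported verbatim as used in the 5hmC literature
#' this package mirrors; under no ties it equals a one-sided p-value, and
#' under a pure null only about 2.5% of features fall below 0.05.
#'
#' @param x,y Numeric vectors for case and control groups (>= 2 values each).
#' @return Named numeric: `p_raw` (two-sided), `p_empirical` (= p_raw / 2).
#' @export
wilcoxon_empirical_p <- function(x, y) {
  stopifnot_config(length(x) >= 2 && length(y) >= 2,
                   "need at least 2 values per group")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    inform("constant pooled values: degenerate rank-sum test, p = 1")
    return(c(p_raw = 1, p_empirical = 0.5))
  }
  exact <- length(x) * length(y) <= 400 && !anyDuplicated(pooled)
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  p <- min(p, 1)
  c(p_raw = p, p_empirical = p / 2)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped
#' at 1 and mapped back to input order.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  stopifnot_config(is.numeric(p) && all(p >= 0 & p <= 1, na.rm = TRUE),
                   "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential table for case versus control
#'
#' Runs [log2_fold_change()] and [wilcoxon_empirical_p()] per feature on
#' normalized (size-factor-scaled) data and attaches BH q-values computed
#' on the empirical p-values, giving one record per feature.
#'
#' @param counts Count tibble or matrix.
#' @param groups Per-sample `case`/`control` labels.
#' @param factors Optional size-factor tibble.
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return A tibble of class `hmc_differential`: `feature_id`, `log2fc`,
#'   `p_raw`, `p_empirical`, `q`.
#' @export
differential_test <- function(counts, groups, factors = NULL, pseudocount = 1) {
  m <- as_feature_matrix(counts)
  groups <- as.character(groups)
  if (is.null(factors)) factors <- size_factors(m, pseudocount = 1)
  lfc <- log2_fold_change(m, groups, factors, pseudocount)
  sf <- setNames(factors$size_factor, factors$sample_id)[colnames(m)]
  scaled <- sweep(m, 2, sf, "/")
  case_idx <- groups == "case"
  pv <- t(apply(scaled, 1, function(v) {
    wilcoxon_empirical_p(v[case_idx], v[!case_idx])
  }))
  out <- tibble(feature_id = lfc$feature_id, log2fc = lfc$log2fc,
                p_raw = pv[, "p_raw"], p_empirical = pv[, "p_empirical"],
                q = bh_fdr(pv[, "p_empirical"]))
  class(out) <- c("hmc_differential", class(out))
  out
}

#' Call hyper-/hypo-hydroxymethylated features
#'
#' Volcano rule with strict inequalities: `hyper` when
#' `log2fc > lfc_min` and `p_empirical < p_max`; `hypo` when
#' `log2fc < -lfc_min` and `p_empirical < p_max`; otherwise `ns`.
#' Defaults (`lfc_min = 0.26`, i.e. a 20% fold change; `p_max = 0.05`)
#' follow the gene-body analysis this package reproduces.
#'
#' @param records A differential tibble from [differential_test()].
#' @param lfc_min,p_max Thresholds (strict).
#' @return `records` with a `direction` column plus attributes
#'   `n_hyper`/`n_hypo`.
#' @export
call_differential <- function(records, lfc_min = 0.26, p_max = 0.05) {
  stopifnot_config(lfc_min > 0 && p_max > 0, "thresholds must be positive")
  dir <- dplyr::case_when(
    records$log2fc > lfc_min & records$p_empirical < p_max ~ "hyper",
    records$log2fc < -lfc_min & records$p_empirical < p_max ~ "hypo",
    .default = "ns"
  )
  out <- dplyr::mutate(records, direction = dir)
  attr(out, "n_hyper") <- sum(dir == "hyper")
  attr(out, "n_hypo") <- sum(dir == "hypo")
  class(out) <- unique(c("hmc_differential", class(out)))
  out
}

#' Logistic covariate screen for candidate features
#'
#' Per feature, fits `status ~ value + age + gender` by logistic regression
#' (age z-scored for conditioning) and keeps features whose Wald p-value
#' for the feature coefficient is below `p_threshold` — the candidate list
#' from which stability selection starts. Features that separate the
#' groups perfectly are kept with `p = 0` and flagged rather than refit,
#' since the screen only ranks candidates.
#'
#' @param values Normalized value tibble/matrix (features x samples) or an
#'   `hmc_norm` object.
#' @param status Case/control labels or 0/1 vector per sample.
#' @param age,gender Per-sample covariates.
#' @param p_threshold Retention threshold (default 0.01).
#' @return Tibble: `feature_id`, `estimate`, `p`, `separation`, `keep`.
#' @export
covariate_screen <- function(values, status, age, gender, p_threshold = 0.01) {
  m <- norm_values(values)
  y <- if (is.numeric(status)) as.integer(status > 0) else
    as.integer(as.character(status) == "case")
  stopifnot_config(length(y) == ncol(m), "one status per sample required")
  age_z <- as.numeric(scale(as.numeric(age)))
  gend <- as.integer(as.factor(gender)) - 1L
  res <- apply(m, 1, function(v) {
    fit <- suppressWarnings(glm(y ~ v + age_z + gend, family = binomial()))
    co <- summary(fit)$coefficients
    est <- co["v", "Estimate"]
    p <- co["v", "Pr(>|z|)"]
    sep <- !fit$converged || abs(est) > 15 ||
      max(abs(fit$linear.predictors)) > 25
    if (sep) p <- 0
    c(est = est, p = p, sep = as.numeric(sep))
  })
  tibble(feature_id = rownames(m), estimate = res["est", ],
         p = res["p", ], separation = res["sep", ] > 0,
         keep = res["p", ] < p_threshold)
}

#' Hierarchical clustering of samples on called features
#'
#' Average-linkage clustering of samples under the distance
#' `1 - Pearson correlation`, computed on the supplied (typically
#' differential) features. Columns are ordered lexicographically by sample
#' id before clustering so ties break deterministically.
#'
#' @param values Value tibble/matrix or `hmc_norm`.
#' @param features Optional feature ids to restrict to.
#' @return List of class `hmc_hclust`: `hclust` (the tree), `order`
#'   (sample ids in dendrogram order), `merge` (merge list).
#' @export
hierarchical_cluster <- function(values, features = NULL) {
  m <- norm_values(values)
  if (!is.null(features)) {
    stopifnot_config(all(features %in% rownames(m)),
                     "unknown feature ids in `features`")
    m <- m[features, , drop = FALSE]
  }
  m <- m[, order(colnames(m)), drop = FALSE]
  if (ncol(m) == 1) {
    return(structure(list(hclust = NULL, order = colnames(m),
                          merge = matrix(numeric(0), 0, 2)),
                     class = "hmc_hclust"))
  }
  cc <- suppressWarnings(cor(m))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "average")
  structure(list(hclust = hc, order = colnames(m)[hc$order], merge = hc$merge),
            class = "hmc_hclust")
}
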