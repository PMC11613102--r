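#' Median-of-ratios library-size factors
#'
#' Estimates one scale factor per sample as the median, over features with
#' all-positive counts, of the ratio of the sample's count to the
#' feature's geometric mean across samples — the internal library-size
#' normalization convention of count-based differential analysis. Factors
#' are rescaled to geometric mean 1 so they are identifiable.
#'
#' @param counts Count tibble (`feature_id` + sample columns) or matrix.
#' @param pseudocount Optional positive value added to every count before
#'   forming ratios; the fallback when no feature is positive in all
#'   samples. Default `NULL` (strict all-positive-row convention).
#' @return Tibble with `sample_id` and `size_factor`.
#' @examples
#' m <- matrix(c(1, 2, 4, 2, 4, 8), nrow = 3) # sample 2 = 2 x sample 1
#' size_factors(m)
#' @export
size_factors <- function(counts, pseudocount = NULL) {
  m <- as_feature_matrix(counts)
  stopifnot_config(all(m >= 0), "counts must be non-negative")
  if (!is.null(pseudocount)) {
    stopifnot_config(pseudocount > 0, "`pseudocount` must be positive")
    m <- m + pseudocount
  }
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste("no feature has positive counts in every sample;",
                "rerun with a pseudocount (e.g. size_factors(x, pseudocount = 1))"),
          class = "hmcprog_config_error")
  }
  logm <- log(m[pos, , drop = FALSE])
  log_geo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - log_geo)))
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Log2-normalized 5hmC matrix
#'
#' Scales counts by per-sample size factors and moves to log2 with a
#' pseudocount: `value = log2(count / size_factor + pseudocount)`.
#'
#' @param counts Count tibble or matrix.
#' @param factors Output of [size_factors()] (computed if `NULL`).
#' @param pseudocount Pseudocount added after scaling (default 1).
#' @return An object of class `hmc_norm`: list with `values` (tibble,
#'   log2 scale), `size_factors`, `pseudocount`, `batch_adjusted`.
#' @export
normalize_log <- function(counts, factors = NULL, pseudocount = 1) {
  m <- as_feature_matrix(counts)
  if (is.null(factors)) factors <- size_factors(m)
  sf <- setNames(factors$size_factor, factors$sample_id)[colnames(m)]
  stopifnot_config(!anyNA(sf) && all(sf > 0),
                   "size factors must be positive and cover every sample")
  vals <- log2(sweep(m, 2, sf, "/") + pseudocount)
  structure(list(values = as_feature_tibble(vals),
                 size_factors = factors, pseudocount = pseudocount,
                 batch_adjusted = FALSE),
            class = "hmc_norm")
}

#' @export
print.hmc_norm <- function(x, ...) {
  cat("<hmc_norm> ", nrow(x$values), " features x ", ncol(x$values) - 1,
      " samples (log2 scale, pseudocount ", x$pseudocount,
      if (x$batch_adjusted) ", batch-adjusted" else "", ")\n", sep = "")
  invisible(x)
}

norm_values <- function(x) {
  if (inherits(x, "hmc_norm")) as_feature_matrix(x$values) else as_feature_matrix(x)
}

#' Parametric empirical-Bayes batch adjustment
#'
#' Removes additive/multiplicative batch effects from a log-scale matrix by
#' the parametric empirical-Bayes location/scale method: per-feature
#' standardization under a model that protects biological covariates,
#' moment-matched normal and inverse-gamma priors on per-batch location and
#' scale, iterated posterior estimates, then subtraction and rescaling.
#' Protecting the case/control design (and age/gender) during estimation
#' prevents the adjustment from absorbing true group differences.
#'
#' @param norm An `hmc_norm` object, or a log-scale matrix/tibble.
#' @param batch Character/factor of batch labels, one per sample.
#' @param covariates Optional data frame of biological covariates to
#'   protect (e.g. group, age, gender); expanded via `model.matrix`.
#' @return Same type as `norm`, with batch-adjusted values.
#' @export
combat_adjust <- function(norm, batch, covariates = NULL) {
  x <- norm_values(norm)
  batch <- as.factor(as.character(batch))
  stopifnot_config(length(batch) == ncol(x),
                   "`batch` must have one label per sample")
  n_per <- table(batch)
  if (any(n_per < 2)) {
    abort(paste0("singleton batch(es): ",
                 paste(names(n_per)[n_per < 2], collapse = ", "),
                 "; every batch needs >= 2 samples"),
          class = "hmcprog_config_error")
  }
  if (nlevels(batch) == 1) {
    return(set_adjusted(norm, x))
  }

  bdes <- model.matrix(~ batch - 1)
  wdes <- NULL
  if (!is.null(covariates)) {
    stopifnot_config(is.data.frame(covariates) && nrow(covariates) == ncol(x),
                     "`covariates` must be a data frame with one row per sample")
    wdes <- model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  }
  design <- cbind(bdes, wdes)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("batch is confounded with covariate(s): ",
                 paste(aliased, collapse = ", ")),
          class = "hmcprog_config_error")
  }

  n <- ncol(x)
  n_b <- as.numeric(n_per)
  B <- nlevels(batch)
  beta <- t(solve(crossprod(design), crossprod(design, t(x))))
  grand <- beta[, seq_len(B), drop = FALSE] %*% (n_b / n)
  var_pooled <- rowSums((x - t(design %*% t(beta)))^2) / n
  var_pooled <- pmax(var_pooled, 1e-12)
  stand_mean <- matrix(grand, nrow(x), n)
  if (!is.null(wdes)) {
    stand_mean <- stand_mean +
      t(wdes %*% t(beta[, -seq_len(B), drop = FALSE]))
  }
  z <- (x - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(solve(crossprod(bdes), crossprod(bdes, t(z))))  # G x B
  # Per-batch scale with the same (maximum-likelihood, n_i) denominator as
  # var_pooled, which makes the adjustment exactly idempotent when the
  # batch effect is a pure shift.
  delta_hat <- sapply(seq_len(B), function(i) {
    zi <- z[, batch == levels(batch)[i], drop = FALSE]
    rowSums((zi - gamma_hat[, i])^2) / n_b[i]
  })
  delta_hat <- pmax(matrix(delta_hat, nrow(x), B), 1e-12)

  eps <- 1e-12
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(B)) {
    g_hat <- gamma_hat[, i]; d_hat <- delta_hat[, i]; ni <- n_b[i]
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m_d <- mean(d_hat); s2_d <- var(d_hat)
    zi <- z[, batch == levels(batch)[i], drop = FALSE]
    t2_degenerate <- !is.finite(t2) || t2 < eps
    d_degenerate <- !is.finite(s2_d) || s2_d < eps
    if (t2_degenerate && d_degenerate) {
      # No feature-to-feature variation to learn priors from: the location
      # posterior collapses onto the shared shift, the scale stays as
      # observed (an identical shift on every feature is removed exactly).
      gamma_star[, i] <- g_bar
      delta_star[, i] <- d_hat
      next
    }
    a_prior <- if (d_degenerate) Inf else (2 * s2_d + m_d^2) / s2_d
    b_prior <- if (d_degenerate) Inf else (m_d * s2_d + m_d^3) / s2_d
    g_new <- g_hat; d_new <- d_hat
    change <- 1
    iter <- 0
    while (change > 1e-4 && iter < 100) {
      iter <- iter + 1
      g_old <- g_new; d_old <- d_new
      g_new <- if (t2_degenerate) rep(g_bar, length(g_hat)) else {
        (ni * t2 * g_hat + d_old * g_bar) / (ni * t2 + d_old)
      }
      d_new <- if (d_degenerate) d_hat else {
        (0.5 * rowSums((zi - g_new)^2) + b_prior) / (ni / 2 + a_prior - 1)
      }
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), eps),
                    abs(d_new - d_old) / pmax(abs(d_old), eps))
    }
    gamma_star[, i] <- g_new
    delta_star[, i] <- d_new
  }

  adj <- z
  for (i in seq_len(B)) {
    sel <- batch == levels(batch)[i]
    adj[, sel] <- (z[, sel, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  adj <- adj * sqrt(var_pooled) + stand_mean
  out <- set_adjusted(norm, adj)
  attr(out, "batch_model") <- list(gamma_hat = gamma_hat, delta_hat = delta_hat,
                                   gamma_star = gamma_star,
                                   delta_star = delta_star, batch = batch)
  out
}

set_adjusted <- function(norm, mat) {
  if (inherits(norm, "hmc_norm")) {
    norm$values <- as_feature_tibble(mat)
    norm$batch_adjusted <- TRUE
    norm
  } else if (is.matrix(norm)) {
    mat
  } else {
    as_feature_tibble(mat)
  }
}
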