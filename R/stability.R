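# Bootstrapped elastic-net stability selection of the gene panel.
#
# The procedure: repeat 100 times — resample the training set with
# replacement stratified by class, choose (alpha, lambda) by stratified
# five-fold cross-validated binomial deviance over a grid, refit on the
# whole resample, score features on a 0-100 importance scale and mark those
# above the importance floor; retain features marked in at least 80% of
# iterations.

#' Configuration for bootstrapped elastic-net stability selection
#'
#' @param n_bootstrap Number of bootstrap iterations (default 100).
#' @param alpha_grid Elastic-net mixing grid inside [0.05, 1]; `alpha = 1`
#'   is the lasso, small alpha approaches ridge.
#' @param lambda_grid Penalty-strength grid inside [1e-5, 1], decreasing.
#' @param n_folds Cross-validation folds (default 5, stratified by class).
#' @param importance_min Importance floor (0-100 scale) a feature must
#'   exceed (strictly) to be marked in an iteration (default 20).
#' @param freq_min Selection frequency needed for the final panel
#'   (default 0.80).
#' @param cv_thresh Coordinate-descent convergence threshold used for the
#'   cross-validation fold fits; final per-resample fits always use 1e-7.
#' @param cv_rule `"min"` (default): the grid point minimizing mean
#'   held-out deviance, ties toward larger lambda then larger alpha;
#'   `"1se"`: the most parsimonious point within one standard error of the
#'   minimum.
#' @param seed Master seed; per-iteration seeds are derived by counter.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(n_bootstrap = 100,
                             alpha_grid = c(0.05, 0.25, 0.5, 0.75, 1),
                             lambda_grid = 10^seq(0, -5, length.out = 30),
                             n_folds = 5,
                             importance_min = 20,
                             freq_min = 0.80,
                             cv_thresh = 1e-5,
                             cv_rule = c("min", "1se"),
                             seed = 1L) {
  cv_rule <- match.arg(cv_rule)
  stopifnot_config(is_count(n_bootstrap) && n_bootstrap >= 1,
                   "`n_bootstrap` must be a positive count")
  stopifnot_config(length(alpha_grid) >= 1 && all(alpha_grid >= 0.05 - 1e-9) &&
                     all(alpha_grid <= 1), "`alpha_grid` must lie in [0.05, 1]")
  stopifnot_config(length(lambda_grid) >= 1 && all(lambda_grid >= 1e-5 - 1e-12) &&
                     all(lambda_grid <= 1 + 1e-12),
                   "`lambda_grid` must lie in [1e-5, 1]")
  stopifnot_config(is_count(n_folds) && n_folds >= 2, "`n_folds` must be >= 2")
  stopifnot_config(freq_min > 0, "`freq_min` must be positive")
  structure(
    list(n_bootstrap = as.integer(n_bootstrap),
         alpha_grid = sort(alpha_grid),
         lambda_grid = sort(lambda_grid, decreasing = TRUE),
         n_folds = as.integer(n_folds),
         importance_min = importance_min, freq_min = freq_min,
         cv_thresh = cv_thresh, cv_rule = cv_rule,
         seed = as.integer(seed)),
    class = "selection_config"
  )
}

check_xy <- function(X, y) {
  stopifnot_config(is.matrix(X) && is.numeric(X), "`X` must be a numeric matrix")
  y <- if (is.numeric(y)) as.integer(y) else
    as.integer(as.character(y) == "case")
  stopifnot_config(all(y %in% c(0L, 1L)) && length(y) == nrow(X),
                   "`y` must be binary with one label per row of X")
  stopifnot_config(length(unique(y)) == 2, "`y` must contain both classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  list(X = X, y = y)
}

#' Elastic-net penalized logistic fit
#'
#' Minimizes mean binomial deviance plus
#' `lambda * (alpha * |beta|_1 + (1 - alpha) * |beta|_2^2 / 2)` with
#' features standardized internally and an unpenalized intercept.
#' Zero-variance features are dropped with a warning (coefficient 0).
#'
#' @param X Sample-by-feature numeric matrix.
#' @param y Binary labels (0/1 or case/control).
#' @param alpha Elastic-net mixing parameter.
#' @param lambda Penalty strength (single value or decreasing path).
#' @param thresh Convergence threshold (default 1e-7).
#' @return List: `beta` (named vector, original scale, at the smallest
#'   lambda), `intercept`, `fit` (the underlying path object).
#' @export
enet_logistic_fit <- function(X, y, alpha, lambda, thresh = 1e-7) {
  d <- check_xy(X, y)
  sds <- apply(d$X, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warn(paste(sum(!keep), "zero-variance feature(s) dropped"))
  }
  Xk <- d$X[, keep, drop = FALSE]
  fit <- glmnet::glmnet(Xk, d$y, family = "binomial", alpha = alpha,
                        lambda = sort(lambda, decreasing = TRUE),
                        standardize = TRUE, thresh = thresh)
  k <- length(fit$lambda)
  beta <- setNames(numeric(ncol(d$X)), colnames(d$X))
  beta[colnames(Xk)] <- as.numeric(fit$beta[, k])
  list(beta = beta, intercept = as.numeric(fit$a0[k]), fit = fit,
       lambda = fit$lambda)
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated choice of (alpha, lambda)
#'
#' Stratified k-fold cross-validation over the full (alpha, lambda) grid,
#' choosing the pair minimizing mean held-out binomial deviance; ties are
#' broken toward the larger lambda, then the larger alpha (the more
#' parsimonious model). The chosen pair is refit on all data at full
#' precision.
#'
#' @param X Sample-by-feature matrix.
#' @param y Binary labels.
#' @param config A [selection_config()].
#' @return List: `alpha`, `lambda`, `beta`, `intercept`, `cv` (tibble of
#'   mean deviance per grid point).
#' @export
cv_select <- function(X, y, config = selection_config()) {
  d <- check_xy(X, y)
  with_seed(config$seed, cv_select_impl(d$X, d$y, config))
}

cv_select_impl <- function(X, y, config) {
  fold <- stratified_folds(y, config$n_folds)
  lambda <- config$lambda_grid
  n_a <- length(config$alpha_grid)
  dev <- matrix(NA_real_, n_a, length(lambda))
  se <- matrix(NA_real_, n_a, length(lambda))
  for (ai in seq_len(n_a)) {
    a <- config$alpha_grid[ai]
    dev_fold <- matrix(NA_real_, config$n_folds, length(lambda))
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = a, lambda = lambda, standardize = TRUE,
                            thresh = config$cv_thresh)
      p <- predict(fit, X[!tr, , drop = FALSE], type = "response")
      # glmnet may stop the path early; carry the last fitted lambda on.
      got <- match(fit$lambda, lambda)
      for (li in seq_along(lambda)) {
        use <- if (li %in% got) which(got == li) else length(fit$lambda)
        dev_fold[f, li] <- binomial_deviance(y[!tr], p[, use])
      }
    }
    dev[ai, ] <- colMeans(dev_fold)
    se[ai, ] <- apply(dev_fold, 2, sd) / sqrt(config$n_folds)
  }
  best <- min(dev)
  cutoff <- if ((config$cv_rule %||% "min") == "1se") {
    at_min <- which(dev == best, arr.ind = TRUE)[1, ]
    best + se[at_min[1], at_min[2]]
  } else {
    best + 1e-12
  }
  cand <- which(dev <= cutoff, arr.ind = TRUE)
  # larger lambda first (grid is decreasing), then larger alpha
  cand <- cand[order(cand[, "col"], -cand[, "row"]), , drop = FALSE]
  ai <- cand[1, "row"]; li <- cand[1, "col"]
  final <- enet_logistic_fit(X, y, alpha = config$alpha_grid[ai],
                             lambda = lambda[seq_len(li)], thresh = 1e-7)
  cv <- tidyr::expand_grid(alpha = config$alpha_grid, lambda = lambda)
  cv$deviance <- as.numeric(t(dev))
  list(alpha = config$alpha_grid[ai], lambda = lambda[li],
       beta = final$beta, intercept = final$intercept, cv = cv)
}

#' Importance scores on a 0-100 scale
#'
#' Max-scaled standardized coefficient magnitudes:
#' `100 * |beta_j| * sd(X_j) / max_k |beta_k| * sd(X_k)`; an all-zero
#' model scores every feature 0.
#'
#' @param beta Named coefficient vector (original scale).
#' @param X The design matrix the fit was produced from.
#' @return Named numeric scores in [0, 100].
#' @export
importance_scores <- function(beta, X) {
  stopifnot_config(length(beta) == ncol(X),
                   "`beta` must have one coefficient per feature")
  raw <- abs(beta) * apply(X, 2, sd)
  if (max(raw) == 0) return(setNames(numeric(length(raw)), names(beta)))
  setNames(100 * raw / max(raw), names(beta))
}

#' Bootstrapped elastic-net stability selection
#'
#' Runs [cv_select()] on class-stratified bootstrap resamples of the
#' training data, marks features with importance strictly above
#' `importance_min` in each iteration, and retains the panel of features
#' marked in at least `freq_min` of iterations.
#'
#' @param X Training sample-by-feature matrix (training split only).
#' @param y Binary training labels.
#' @param config A [selection_config()].
#' @return Object of class `hmc_selection`: `frequency` tibble
#'   (`feature_id`, `frequency`), `panel` (retained feature ids),
#'   `iterations` tibble (per-bootstrap alpha, lambda, number marked),
#'   `config`.
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- matrix(rnorm(46 * 30), 46, 30)
#' y <- rep(c(1, 0), c(14, 32))
#' X[, 1] <- X[, 1] + 2 * y
#' sel <- stability_select(X, y, selection_config(n_bootstrap = 10, seed = 2))
#' sel$panel
#' }
#' @export
stability_select <- function(X, y, config = selection_config()) {
  d <- check_xy(X, y)
  X <- d$X; y <- d$y
  marks <- matrix(FALSE, config$n_bootstrap, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  iters <- vector("list", config$n_bootstrap)
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  for (b in seq_len(config$n_bootstrap)) {
    seed_b <- derive_seed(config$seed, paste0("bootstrap_", b))
    res <- with_seed(seed_b, {
      take <- c(sample(idx1, length(idx1), replace = TRUE),
                sample(idx0, length(idx0), replace = TRUE))
      Xb <- X[take, , drop = FALSE]
      yb <- y[take]
      sel <- cv_select_impl(Xb, yb, config)
      imp <- importance_scores(sel$beta, Xb)
      list(marked = imp > config$importance_min, alpha = sel$alpha,
           lambda = sel$lambda)
    })
    marks[b, ] <- res$marked
    iters[[b]] <- tibble(bootstrap = b, alpha = res$alpha,
                         lambda = res$lambda, n_marked = sum(res$marked))
  }
  freq <- colMeans(marks)
  structure(
    list(frequency = tibble(feature_id = colnames(X), frequency = unname(freq)),
         panel = colnames(X)[freq >= config$freq_min],
         iterations = dplyr::bind_rows(iters),
         config = config),
    class = "hmc_selection"
  )
}

#' @export
print.hmc_selection <- function(x, ...) {
  cat("<hmc_selection> ", x$config$n_bootstrap, " bootstraps over ",
      nrow(x$frequency), " features; panel of ", length(x$panel),
      if (length(x$panel)) paste0(": ", paste(x$panel, collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}
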