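# Final multivariable logistic risk model on the selected gene panel plus
# clinical covariates, with ROC/AUC evaluation, bootstrap confidence
# intervals and a specificity-anchored decision cutoff.

#' Stratified train/validation split
#'
#' Randomly assigns samples to training and validation sets, stratified by
#' case status, so a 2/3 ratio on 21 cases / 48 controls yields 14 + 32
#' training and 7 + 16 validation samples.
#'
#' @param samples Sample metadata tibble with a `group` column
#'   (`case`/`control`).
#' @param ratio Training fraction, strictly between 0 and 1 (default 2/3).
#' @param seed Integer seed.
#' @return `samples` with a `split` column (`train`/`validation`).
#' @export
split_train_valid <- function(samples, ratio = 2 / 3, seed = 1L) {
  stopifnot_config(is.data.frame(samples) && "group" %in% names(samples),
                   "`samples` needs a `group` column")
  stopifnot_config(is.numeric(ratio) && ratio > 0 && ratio < 1,
                   "`ratio` must be strictly between 0 and 1 (both splits non-empty)")
  with_seed(seed, {
    split <- rep("validation", nrow(samples))
    for (g in unique(samples$group)) {
      idx <- which(samples$group == g)
      n_train <- round(ratio * length(idx))
      stopifnot_config(n_train >= 1 && n_train < length(idx),
                       "split leaves an empty stratum; adjust `ratio`")
      split[sample(idx, n_train)] <- "train"
    }
    dplyr::mutate(samples, split = split)
  })
}

#' Unpenalized logistic regression by IRLS
#'
#' Iteratively reweighted least squares for maximum-likelihood logistic
#' regression (tolerance 1e-8, at most 50 iterations). If separation is
#' detected (diverging coefficients or non-convergence), the model is
#' refit with a ridge penalty and flagged. The default fallback penalty is
#' 1 on the information scale — strong enough to pin the separating
#' direction to the data rather than to numerical noise (a nominal 1e-6
#' penalty leaves coefficients of order 1e3 along an arbitrary separating
#' hyperplane); predictors are expected on roughly unit scale.
#'
#' @param X Numeric design matrix (no intercept column; one is added).
#' @param y Binary response.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Iteration cap.
#' @param separation_ridge Ridge penalty used for the refit when
#'   separation is detected (default 1).
#' @return List: `coefficients` (named, `(Intercept)` first),
#'   `fitted` (probabilities), `separation` (logical flag),
#'   `converged`, `iterations`.
#' @export
irls_fit <- function(X, y, tol = 1e-8, max_iter = 50, separation_ridge = 1) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  y <- if (is.numeric(y)) as.numeric(y) else
    as.numeric(as.character(y) == "case")
  stopifnot_config(all(y %in% c(0, 1)), "`y` must be binary")
  if (is.null(colnames(X)) && ncol(X) > 0) colnames(X) <- paste0("x", seq_len(ncol(X)))
  # constant columns carry no information and would only make the
  # information matrix singular; they get coefficient 0
  keep <- if (ncol(X) > 0) apply(X, 2, function(v) var(v) > 0) else logical(0)
  X_all <- X
  X <- X[, keep, drop = FALSE]
  D <- cbind(`(Intercept)` = 1, X)
  run <- function(ridge) {
    beta <- numeric(ncol(D))
    converged <- FALSE
    diverged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      eta <- drop(D %*% beta)
      p <- 1 / (1 + exp(-eta))
      w <- pmax(p * (1 - p), 1e-10)
      z <- eta + (y - p) / w
      H <- crossprod(D, D * w) + diag(ridge, ncol(D))
      beta_new <- tryCatch(solve(H, crossprod(D, w * z)),
                           error = function(e) NULL)
      if (is.null(beta_new)) { diverged <- TRUE; break }
      delta <- max(abs(beta_new - beta))
      beta <- drop(beta_new)
      if (max(abs(beta)) > 1e4 || max(abs(D %*% beta)) > 100) {
        diverged <- TRUE
        break
      }
      if (delta < tol) { converged <- TRUE; break }
    }
    list(beta = beta, converged = converged, diverged = diverged, it = it)
  }
  fit <- run(0)
  separation <- fit$diverged || !fit$converged
  if (separation) fit <- run(separation_ridge)
  beta <- setNames(numeric(ncol(X_all) + 1),
                   c("(Intercept)", colnames(X_all)))
  beta[colnames(D)] <- fit$beta
  eta <- drop(cbind(`(Intercept)` = 1, X_all) %*% beta)
  list(coefficients = beta, fitted = 1 / (1 + exp(-eta)),
       separation = separation, converged = fit$converged,
       iterations = fit$it)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Thresholds sweep the observed scores from high to low; tied scores step
#' the curve diagonally (simultaneously), so the trapezoidal area equals
#' the Mann-Whitney probability with the usual 1/2 tie credit.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param labels Binary labels (1/case = positive).
#' @return List of class `hmc_roc`: `curve` tibble
#'   (`threshold`, `fpr`, `tpr`) from (0,0) to (1,1), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(as.character(labels) == "case")
  stopifnot_config(length(scores) == length(y) && all(y %in% 0:1),
                   "`labels` must be binary, one per score")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopifnot_config(n1 > 0 && n0 > 0, "need both classes to build a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y == 0), numeric(1))
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fp / n0),
                  tpr = c(0, tp / n1))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "hmc_roc")
}

#' Stratified bootstrap percentile CI for the AUC
#'
#' Resamples cases and controls separately with replacement, recomputes the
#' trapezoidal AUC, and reports the percentile interval clipped to [0, 1].
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `lower`, `upper`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000, seed = 1L, conf = 0.95) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(as.character(labels) == "case")
  i1 <- which(y == 1); i0 <- which(y == 0)
  with_seed(seed, {
    aucs <- vapply(seq_len(n_boot), function(b) {
      take <- c(sample(i1, length(i1), TRUE), sample(i0, length(i0), TRUE))
      roc_auc(scores[take], y[take])$auc
    }, numeric(1))
    q <- quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    c(lower = max(0, q[1]), upper = min(1, q[2]))
  })
}

#' Decision cutoff anchored at validation specificity
#'
#' Among thresholds achieving at least `min_specificity` on the validation
#' set (score >= cutoff called positive), picks the one maximizing
#' sensitivity; ties resolve to the larger threshold.
#'
#' @param scores Validation risk scores.
#' @param labels Validation labels.
#' @param min_specificity Specificity floor (default 0.90).
#' @return Named numeric: `cutoff`, `sensitivity`, `specificity` (on the
#'   validation set).
#' @export
choose_cutoff <- function(scores, labels, min_specificity = 0.90) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(as.character(labels) == "case")
  stopifnot_config(sum(y == 0) > 0 && sum(y == 1) > 0,
                   "validation set must contain both classes")
  cand <- sort(unique(c(scores, max(scores) + 1)), decreasing = TRUE)
  sentinel <- cand == max(scores) + 1
  stats <- vapply(cand, function(t) {
    c(sens = mean(scores[y == 1] >= t), spec = mean(scores[y == 0] < t))
  }, numeric(2))
  ok <- stats["spec", ] >= min_specificity
  if (!any(ok & !sentinel)) {
    abort(paste0("no observed-score threshold reaches specificity ",
                 min_specificity, " on the validation set (",
                 length(unique(scores)),
                 " distinct scores); scores may be degenerate"),
          class = "hmcprog_config_error")
  }
  best_sens <- max(stats["sens", ok])
  feasible <- which(ok & stats["sens", ] >= best_sens - 1e-12)
  pick <- feasible[which.max(cand[feasible])]
  c(cutoff = unname(cand[pick]), sensitivity = unname(stats["sens", pick]),
    specificity = unname(stats["spec", pick]))
}

#' Fit and evaluate the progression risk model end to end
#'
#' Builds the design matrix from the selected gene panel plus clinical
#' covariates (gender, age as z-score, lesion type as indicator columns
#' with inflammation as reference, and optionally a fixed-coefficient
#' cohort log-hazard offset), fits unpenalized logistic regression on the
#' training split by [irls_fit()], evaluates ROC/AUC with stratified
#' bootstrap CIs on both splits, anchors the decision cutoff at >= 90%
#' validation specificity, and reports sensitivity/specificity on all
#' samples pooled.
#'
#' @param values Normalized value tibble/matrix or `hmc_norm`
#'   (features x samples).
#' @param samples Sample tibble with `sample_id`, `group`, `age`, `gender`,
#'   `lesion` and `split` columns (see [split_train_valid()]).
#' @param panel Character vector of panel feature ids (may be empty:
#'   covariates-only model).
#' @param covariates Clinical covariates to include (default
#'   `c("gender", "age", "lesion")`).
#' @param offset Optional per-sample offset added to the linear predictor
#'   with coefficient fixed at 1 (e.g. a Cox linear predictor from the
#'   cohort model); default `NULL`.
#' @param min_specificity Validation specificity floor for the cutoff.
#' @param n_boot,seed Bootstrap settings for the AUC CIs.
#' @return Object of class `hmc_risk_model`: coefficients, per-split AUC
#'   and CI, cutoff, pooled sensitivity/specificity, scores tibble.
#' @export
fit_risk_model <- function(values, samples, panel,
                           covariates = c("gender", "age", "lesion"),
                           offset = NULL, min_specificity = 0.90,
                           n_boot = 2000, seed = 1L) {
  m <- norm_values(values)
  need <- c("sample_id", "group", "split")
  stopifnot_config(all(need %in% names(samples)),
                   paste("`samples` needs columns:", paste(need, collapse = ", ")))
  stopifnot_config(all(samples$sample_id %in% colnames(m)),
                   "every sample must have a column in `values`")
  stopifnot_config(all(panel %in% rownames(m)),
                   "panel features missing from `values`")
  X_panel <- t(m[panel, samples$sample_id, drop = FALSE])
  X_cov <- NULL
  if ("gender" %in% covariates) {
    X_cov <- cbind(X_cov, gender_male = as.numeric(samples$gender == "male"))
  }
  if ("age" %in% covariates) {
    X_cov <- cbind(X_cov, age_z = as.numeric(scale(as.numeric(samples$age))))
  }
  if ("lesion" %in% covariates) {
    X_cov <- cbind(X_cov,
                   lesion_atrophy_im = as.numeric(samples$lesion == "atrophy_im"),
                   lesion_dysplasia = as.numeric(samples$lesion == "dysplasia"))
  }
  X <- cbind(X_panel, X_cov)
  y <- as.numeric(samples$group == "case")
  tr <- samples$split == "train"
  va <- samples$split == "validation"
  stopifnot_config(any(tr) && any(va), "both train and validation splits required")

  if (!is.null(offset)) {
    stopifnot_config(length(offset) == nrow(samples),
                     "`offset` must have one value per sample")
    # fixed-coefficient offset: fit on y with offset absorbed via eta
    fit <- irls_fit_offset(X[tr, , drop = FALSE], y[tr], offset[tr])
    eta <- drop(cbind(1, X) %*% fit$coefficients) + offset
  } else {
    fit <- irls_fit(X[tr, , drop = FALSE], y[tr])
    eta <- drop(cbind(1, X) %*% fit$coefficients)
  }
  # Risk scores are the linear predictor: monotone in the fitted
  # probability but free of the exact ties that probability saturation
  # creates under separation (ties would cost AUC half-credit and can make
  # the specificity-anchored cutoff infeasible).
  score <- eta

  roc_tr <- roc_auc(score[tr], y[tr])
  roc_va <- roc_auc(score[va], y[va])
  ci_tr <- auc_ci(score[tr], y[tr], n_boot, derive_seed(seed, "ci_train"))
  ci_va <- auc_ci(score[va], y[va], n_boot, derive_seed(seed, "ci_valid"))
  cut <- tryCatch(choose_cutoff(score[va], y[va], min_specificity),
                  hmcprog_config_error = function(e) {
                    warn(paste("no usable cutoff:", conditionMessage(e)))
                    c(cutoff = NA_real_, sensitivity = NA_real_,
                      specificity = NA_real_)
                  })
  all_sens <- mean(score[y == 1] >= cut["cutoff"])
  all_spec <- mean(score[y == 0] < cut["cutoff"])

  structure(
    list(coefficients = fit$coefficients, separation = fit$separation,
         train_auc = roc_tr$auc, train_auc_ci = ci_tr,
         validation_auc = roc_va$auc, validation_auc_ci = ci_va,
         roc_train = roc_tr, roc_validation = roc_va,
         cutoff = unname(cut["cutoff"]),
         sensitivity_all = all_sens, specificity_all = all_spec,
         panel = panel,
         scores = tibble(sample_id = samples$sample_id, score = score,
                         probability = 1 / (1 + exp(-score)),
                         group = samples$group, split = samples$split)),
    class = "hmc_risk_model"
  )
}

irls_fit_offset <- function(X, y, offset, tol = 1e-8, max_iter = 50) {
  # IRLS with a fixed offset in the linear predictor.
  D <- cbind(`(Intercept)` = 1, X)
  beta <- numeric(ncol(D))
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(D %*% beta) + offset
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- (eta - offset) + (y - p) / w
    beta_new <- tryCatch(
      solve(crossprod(D, D * w) + diag(1e-10, ncol(D)), crossprod(D, w * z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (max(abs(beta)) > 1e4) break
    if (delta < tol) { converged <- TRUE; break }
  }
  list(coefficients = setNames(beta, colnames(D)), separation = !converged,
       converged = converged, iterations = it)
}

#' @export
print.hmc_risk_model <- function(x, ...) {
  cat("<hmc_risk_model> panel of ", length(x$panel), " + clinical covariates\n",
      "  training AUC ", round_half_up(100 * x$train_auc, 1), "% (",
      round_half_up(100 * x$train_auc_ci[["lower"]], 1), "-",
      round_half_up(100 * x$train_auc_ci[["upper"]], 1), "%)\n",
      "  validation AUC ", round_half_up(100 * x$validation_auc, 1), "% (",
      round_half_up(100 * x$validation_auc_ci[["lower"]], 1), "-",
      round_half_up(100 * x$validation_auc_ci[["upper"]], 1), "%)\n",
      "  cutoff ", signif(x$cutoff, 4), ": all-sample sensitivity ",
      round_half_up(100 * x$sensitivity_all, 1), "%, specificity ",
      round_half_up(100 * x$specificity_all, 1), "%\n", sep = "")
  invisible(x)
}
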