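small_cfg <- function(n_bootstrap = 10, ...) {
  selection_config(n_bootstrap = n_bootstrap,
                   alpha_grid = c(0.05, 0.5, 1),
                   lambda_grid = 10^seq(0, -5, length.out = 12), ...)
}

test_that("full shrinkage gives the empty model with prevalence intercept", {
  set.seed(30)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(1, 0), c(10, 30))
  fit <- enet_logistic_fit(X, y, alpha = 1, lambda = 5)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, log(10 / 30), tolerance = 1e-6)
})

test_that("near-ridge tiny-lambda fit approaches the unpenalized IRLS fit", {
  set.seed(31)
  X <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  beta_true <- c(1, -0.5, 0.8, 0)
  y <- rbinom(300, 1, 1 / (1 + exp(-(X %*% beta_true))))
  fit <- enet_logistic_fit(X, y, alpha = 0.05,
                           lambda = 10^seq(0, -5, length.out = 30))
  ref <- irls_fit(X, y)
  expect_lt(max(abs(fit$beta - ref$coefficients[-1])), 1e-2)
  expect_lt(abs(fit$intercept - ref$coefficients[1]), 1e-2)
})

test_that("the informative feature dominates the lasso path", {
  set.seed(32)
  X <- matrix(rnorm(60 * 21), 60, 21, dimnames = list(NULL, paste0("f", 1:21)))
  y <- rep(c(1, 0), each = 30)
  X[, 1] <- X[, 1] + 1.5 * y
  fit <- enet_logistic_fit(X, y, alpha = 1,
                           lambda = 10^seq(0, -2, length.out = 20))
  expect_equal(which.max(abs(fit$beta)), c(f1 = 1))
})

test_that("zero-variance features are dropped with a warning", {
  set.seed(33)
  X <- cbind(a = rnorm(40), b = rep(2, 40), c = rnorm(40))
  y <- rbinom(40, 1, 0.4)
  expect_warning(fit <- enet_logistic_fit(X, y, 0.5, 0.01), "zero-variance")
  expect_equal(unname(fit$beta["b"]), 0)
  expect_error(enet_logistic_fit(X, c(y[-1], 2), 0.5, 0.01),
               class = "hmcprog_config_error")
})

test_that("importance scores follow the max-scaled standardized magnitude", {
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- scale(X)  # unit sd
  expect_equal(unname(importance_scores(c(a = 2, b = 1, c = 0), X)),
               c(100, 50, 0), tolerance = 1e-6)
  expect_equal(unname(importance_scores(c(a = 0, b = 0, c = 0.3), X))[3], 100)
  expect_equal(unname(importance_scores(c(a = 0, b = 0, c = 0), X)),
               c(0, 0, 0))
  # two equal standardized effects tie at 100
  expect_equal(unname(importance_scores(c(a = 1, b = 1, c = 0), X))[1:2],
               c(100, 100), tolerance = 1e-6)
})

test_that("cv_select recovers a strong planted support and is seed-stable", {
  set.seed(34)
  X <- matrix(rnorm(60 * 20), 60, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c(1, 0), each = 30)
  X[, 1:3] <- X[, 1:3] + outer(y, rep(1.5, 3))
  cfg <- small_cfg(seed = 35)
  sel1 <- cv_select(X, y, cfg)
  sel2 <- cv_select(X, y, cfg)
  expect_identical(sel1[c("alpha", "lambda", "beta")],
                   sel2[c("alpha", "lambda", "beta")])
  expect_true(all(abs(sel1$beta[1:3]) > 0))
})

test_that("a single bootstrap yields 0/1 frequencies equal to its marks", {
  set.seed(36)
  X <- matrix(rnorm(46 * 15), 46, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- rep(c(1, 0), c(14, 32))
  X[, 2] <- X[, 2] + 2 * y
  sel <- stability_select(X, y, small_cfg(n_bootstrap = 1, seed = 37))
  expect_true(all(sel$frequency$frequency %in% c(0, 1)))
  expect_setequal(sel$panel,
                  sel$frequency$feature_id[sel$frequency$frequency == 1])
})

test_that("a dominant feature is selected at high frequency", {
  set.seed(38)
  X <- matrix(rnorm(46 * 30), 46, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- rep(c(1, 0), c(14, 32))
  X[, 5] <- X[, 5] + 2 * y
  sel <- stability_select(X, y, small_cfg(seed = 39))
  expect_gte(sel$frequency$frequency[sel$frequency$feature_id == "f5"], 0.95)
  expect_true("f5" %in% sel$panel)
})

test_that("the panel is invariant to column order and feature rescaling", {
  set.seed(40)
  X <- matrix(rnorm(46 * 12), 46, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- rep(c(1, 0), c(14, 32))
  X[, 3] <- X[, 3] + 1.8 * y
  cfg <- small_cfg(seed = 41)
  base <- stability_select(X, y, cfg)
  perm <- sample(ncol(X))
  shuffled <- stability_select(X[, perm], y, cfg)
  expect_setequal(base$panel, shuffled$panel)
  scaled <- X
  scaled[, 3] <- scaled[, 3] * 50
  rescaled <- stability_select(scaled, y, cfg)
  expect_setequal(base$panel, rescaled$panel)
})

test_that("selection frequency is monotone in the planted effect size", {
  freqs <- vapply(c(0.1, 0.8, 2), function(delta) {
    set.seed(42)
    X <- matrix(rnorm(46 * 300), 46, 300,
                dimnames = list(NULL, sprintf("f%03d", 1:300)))
    y <- rep(c(1, 0), c(14, 32))
    X[, 1] <- X[, 1] + delta * y
    sel <- stability_select(X, y, small_cfg(n_bootstrap = 20, seed = 43))
    sel$frequency$frequency[1]
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
  expect_gt(freqs[3], freqs[1])
})

test_that("freq_min boundaries return everything ever marked or nothing", {
  set.seed(44)
  X <- matrix(rnorm(46 * 10), 46, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c(1, 0), c(14, 32))
  X[, 1] <- X[, 1] + 2 * y
  cfg_all <- small_cfg(seed = 45, freq_min = 1e-9)
  sel_all <- stability_select(X, y, cfg_all)
  marked_ever <- sel_all$frequency$feature_id[sel_all$frequency$frequency > 0]
  expect_setequal(sel_all$panel, marked_ever)
  cfg_none <- small_cfg(seed = 45, freq_min = 1.5)
  expect_length(stability_select(X, y, cfg_none)$panel, 0)
})

test_that("tidiers expose frequencies and panel size", {
  set.seed(46)
  X <- matrix(rnorm(46 * 8), 46, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(1, 0), c(14, 32))
  sel <- stability_select(X, y, small_cfg(n_bootstrap = 5, seed = 47))
  td <- tidy(sel)
  expect_true(all(td$frequency >= 0 & td$frequency <= 1))
  gl <- glance(sel)
  expect_equal(gl$n_bootstrap, 5)
  expect_equal(gl$n_features, 8)
})
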