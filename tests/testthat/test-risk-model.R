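test_that("stratified split reproduces the 14/32 + 7/16 layout", {
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:69),
                            group = rep(c("case", "control"), c(21, 48)))
  sp <- split_train_valid(samples, seed = 3)
  expect_equal(sum(sp$split == "train" & sp$group == "case"), 14)
  expect_equal(sum(sp$split == "train" & sp$group == "control"), 32)
  expect_equal(sum(sp$split == "validation" & sp$group == "case"), 7)
  expect_equal(sum(sp$split == "validation" & sp$group == "control"), 16)
  expect_identical(sp, split_train_valid(samples, seed = 3))
  expect_error(split_train_valid(samples, ratio = 1),
               class = "hmcprog_config_error")
})

test_that("IRLS matches closed forms and glm", {
  # intercept-only: 7 of 23 positive
  y <- rep(c(1, 0), c(7, 16))
  fit <- irls_fit(matrix(numeric(0), 23, 0), y)
  expect_equal(unname(fit$coefficients[1]), log(7 / 16), tolerance = 1e-8)
  # balanced 2x2: coefficient = log odds ratio
  x <- rep(c(0, 1), each = 20)
  y2 <- c(rep(c(1, 0), c(5, 15)), rep(c(1, 0), c(12, 8)))
  fit2 <- irls_fit(matrix(x, ncol = 1), y2)
  or <- (12 / 8) / (5 / 15)
  expect_equal(unname(fit2$coefficients[2]), log(or), tolerance = 1e-6)
  # random design against glm
  set.seed(50)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y3 <- rbinom(200, 1, plogis(0.3 + X %*% c(0.5, -1, 0.2)))
  fit3 <- irls_fit(X, y3)
  ref <- glm(y3 ~ X, family = binomial())
  expect_equal(unname(fit3$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_false(fit3$separation)
})

test_that("separated designs are flagged but stay finite", {
  x <- c(rnorm(10, -3), rnorm(10, 3))
  y <- rep(c(0, 1), each = 10)
  fit <- irls_fit(matrix(x, ncol = 1), y)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("trapezoidal AUC equals the Mann-Whitney identity", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  # exhaustive small cases with ties
  set.seed(51)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    scores <- sample(1:4, n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels)$auc,
                 oracle_auc_mw(scores, labels), tolerance = 1e-12)
  }
})

test_that("null scores give AUC near 0.5 and a valid curve", {
  set.seed(52)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, 0.4)
  roc <- roc_auc(scores, labels)
  expect_lt(abs(roc$auc - 0.5), 0.05)
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[1], 0)
  expect_equal(utils::tail(roc$curve$fpr, 1), 1)
  expect_equal(utils::tail(roc$curve$tpr, 1), 1)
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(diff(roc$curve$tpr) >= 0))
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.3)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("bootstrap AUC interval behaves as a percentile CI", {
  # perfect separation collapses to (1,1)
  ci <- auc_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), n_boot = 200,
               seed = 4)
  expect_equal(unname(ci), c(1, 1))
  set.seed(54)
  scores <- c(rnorm(25, 1), rnorm(25))
  labels <- rep(c(1, 0), each = 25)
  auc <- roc_auc(scores, labels)$auc
  ci2 <- auc_ci(scores, labels, n_boot = 500, seed = 5)
  expect_lte(ci2[["lower"]], auc)
  expect_gte(ci2[["upper"]], auc)
  # interval shrinks with n
  big <- c(rnorm(250, 1), rnorm(250))
  lab_big <- rep(c(1, 0), each = 250)
  ci3 <- auc_ci(big, lab_big, n_boot = 500, seed = 6)
  expect_lt(diff(unname(ci3)), diff(unname(ci2)))
})

test_that("cutoff selection honours the specificity floor", {
  # separated validation scores: cutoff between groups, sens = spec = 1
  sc <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  lb <- c(0, 0, 0, 1, 1)
  cut <- choose_cutoff(sc, lb)
  expect_equal(unname(cut["sensitivity"]), 1)
  expect_equal(unname(cut["specificity"]), 1)
  expect_gt(unname(cut["cutoff"]), 0.3)
  # 16 controls: feasibility means >= 15 below the cutoff
  set.seed(55)
  sc2 <- c(runif(16), runif(7, 0.3, 1.3))
  lb2 <- rep(c(0, 1), c(16, 7))
  cut2 <- choose_cutoff(sc2, lb2, 0.90)
  expect_gte(sum(sc2[lb2 == 0] < cut2["cutoff"]), 15)
  expect_gte(unname(cut2["specificity"]), 15 / 16)
  # degenerate identical scores cannot reach the floor
  expect_error(choose_cutoff(rep(0.4, 10), rep(c(0, 1), 5)),
               class = "hmcprog_config_error")
})

test_that("an all-zero panel feature leaves fitted probabilities unchanged", {
  set.seed(56)
  sim <- simulate_counts(hmc_sim_config(n_features = 40, n_case = 21,
                                        n_control = 48,
                                        frac_differential = 0.2,
                                        delta_log2fc = 1, seed = 57))
  nrm <- normalize_log(sim$counts)
  smp <- split_train_valid(sim$samples, seed = 58)
  panel <- sim$truth$differential_feature_ids[1:3]
  m1 <- fit_risk_model(nrm, smp, panel, n_boot = 100, seed = 59)
  m_zero <- as_matrix <- as.matrix(nrm$values[-1])
  rownames(m_zero) <- nrm$values$feature_id
  m_zero <- rbind(m_zero, zzz_zero = 0)
  m2 <- fit_risk_model(m_zero, smp, c(panel, "zzz_zero"), n_boot = 100,
                       seed = 59)
  expect_equal(m1$scores$score, m2$scores$score, tolerance = 1e-4)
})

test_that("permuted labels give chance-level validation AUC", {
  set.seed(60)
  aucs <- replicate(15, {
    sim <- simulate_counts(hmc_sim_config(n_features = 30, n_case = 21,
                                          n_control = 48,
                                          frac_differential = 0,
                                          seed = sample.int(1e6, 1)))
    smp <- sim$samples
    smp$group <- sample(smp$group)
    smp <- split_train_valid(smp, seed = sample.int(1e6, 1))
    nrm <- normalize_log(sim$counts)
    fit <- fit_risk_model(nrm, smp, panel = sim$counts$feature_id[1:3],
                          n_boot = 50, seed = sample.int(1e6, 1))
    fit$validation_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("risk-model glance reports AUCs, cutoff and pooled metrics", {
  sim <- simulate_counts(hmc_sim_config(n_features = 30, n_case = 21,
                                        n_control = 48,
                                        frac_differential = 0.2,
                                        delta_log2fc = 1.5, seed = 61))
  smp <- split_train_valid(sim$samples, seed = 62)
  nrm <- normalize_log(sim$counts)
  fit <- fit_risk_model(nrm, smp, sim$truth$differential_feature_ids[1:4],
                        n_boot = 100, seed = 63)
  gl <- glance(fit)
  expect_true(gl$train_auc >= gl$train_auc_low &&
                gl$train_auc <= gl$train_auc_high)
  expect_true(gl$validation_auc >= 0 && gl$validation_auc <= 1)
  expect_true(gl$specificity_all >= 0 && gl$specificity_all <= 1)
  td <- tidy(fit)
  expect_true("(Intercept)" %in% td$term)
})
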