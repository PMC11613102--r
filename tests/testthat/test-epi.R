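test_that("person-years arithmetic is exact on hand examples", {
  co <- tibble::tibble(lesion = "inflammation", gender = "male",
                       age_group = "<50", time = c(3, 7), event = c(1, 0))
  py <- person_years(co)
  expect_equal(py$person_years, 10)
  expect_equal(py$rate_per_1000py, 100)
  co0 <- dplyr::mutate(co, event = 0L)
  expect_equal(person_years(co0)$rate_per_1000py, 0)
})

test_that("incidence rate matches the exponential closed form", {
  h <- 0.02
  sim <- simulate_cohort(cohort_sim_config(
    n_patients = 10000, baseline_hazard = h,
    log_hazard_ratios = list(lesion = c(inflammation = 0, atrophy_im = 0,
                                        dysplasia = 0),
                             gender = c(male = 0, female = 0),
                             age_group = c("<50" = 0, "50-59" = 0,
                                           "60-69" = 0, "70+" = 0)),
    seed = 70))
  py <- person_years(sim$cohort)
  se <- sqrt(py$events) / py$person_years * 1000
  expect_lt(abs(py$rate_per_1000py - 1000 * h), 3 * se)
})

test_that("Kaplan-Meier matches the hand product-limit on 5 patients", {
  times <- c(1, 2, 3, 4, 5)
  events <- c(1, 0, 1, 0, 0)
  co <- tibble::tibble(lesion = "x", gender = "m", age_group = "<50",
                       time = times, event = events)
  km <- km_cumulative_incidence(co)
  at <- function(t) km$cum_incidence[km$time == t]
  expect_equal(at(1), 1 / 5)
  expect_equal(at(3), 1 / 5 + (4 / 5) * (1 / 3))
  # no censoring: 1 - empirical survival exactly
  co2 <- tibble::tibble(lesion = "x", gender = "m", age_group = "<50",
                        time = c(2, 4, 6, 8), event = 1L)
  km2 <- km_cumulative_incidence(co2)
  expect_equal(km2$cum_incidence, c(0.25, 0.5, 0.75, 1))
  # all censored: flat zero
  co3 <- dplyr::mutate(co2, event = 0L)
  km3 <- km_cumulative_incidence(co3)
  expect_true(all(km3$cum_incidence == 0))
  # oracle comparison on a random fixture
  set.seed(71)
  co4 <- tibble::tibble(lesion = "x", gender = "m", age_group = "<50",
                        time = round(rexp(60, 0.2), 3) + 0.01,
                        event = rbinom(60, 1, 0.6))
  km4 <- km_cumulative_incidence(co4)
  orc <- oracle_km(co4$time, co4$event)
  got <- km4[km4$n_event > 0, ]
  expect_equal(got$survival, orc$survival[match(got$time, orc$time)],
               tolerance = 1e-12)
})

test_that("Cox fit is calibrated under the null", {
  set.seed(72)
  p <- replicate(60, {
    co <- tibble::tibble(lesion = "x", gender = sample(c("m", "f"), 400, TRUE),
                         age_group = "<50", time = rexp(400, 0.05),
                         event = rbinom(400, 1, 0.7))
    tidy(cox_ph_fit(co, "gender"))$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.08)
})

test_that("Cox partial likelihood matches the single-event closed form", {
  # one event among two subjects at risk, binary covariate: the log partial
  # likelihood at beta is b x1 - log(exp(b x1) + exp(b x2)); at beta = 0 it
  # is -log(2)
  co <- data.frame(time = c(1, 2), event = c(1L, 0L), x = c(1, 0))
  fit0 <- suppressWarnings(survival::coxph(
    survival::Surv(time, event) ~ x, data = co, ties = "breslow",
    init = 0, control = survival::coxph.control(iter.max = 0)))
  expect_equal(fit0$loglik[1], -log(2), tolerance = 1e-12)
  # the monotone-likelihood direction (x = 1 for the only event) must be
  # rejected with a convergence error by the wrapper
  co2 <- tibble::tibble(lesion = "x", gender = "m", age_group = "<50",
                        time = c(1, 2), event = c(1L, 0L), x = c(1, 0))
  expect_error(cox_ph_fit(co2, "x"), class = "hmcprog_fit_error")
  expect_error(cox_ph_fit(dplyr::mutate(co2, event = 0L), "x"),
               class = "hmcprog_config_error")
})

test_that("nomogram points scale to 100 with zero at reference levels", {
  set.seed(73)
  n <- 4000
  g <- sample(c("a_low", "b_high"), n, TRUE)
  s <- sample(c("m", "f"), n, TRUE)
  h <- 0.01 * exp(log(4) * (g == "b_high") + log(2) * (s == "f"))
  co <- tibble::tibble(lesion = "x", gender = s, age_group = "<50",
                       time = pmin(rexp(n, h), 20),
                       event = as.integer(rexp(n, h) <= 20), grp = g)
  co$time <- pmin(co$time, 20)
  fit <- cox_ph_fit(co, c("grp", "gender"))
  nom <- nomogram_points(fit)
  pts <- nom$points
  expect_equal(pts$points[pts$level == "a_low"], 0)
  expect_equal(max(pts$points), 100)
  # beta ratio log2/log4 = 0.5 -> ~50 points for the weaker covariate
  weaker <- pts$points[pts$term == "gender" & pts$level == "f"]
  expect_equal(weaker, 50, tolerance = 12)
  # survival probabilities decrease with points and horizon
  s_low <- nom$survival_at(0, 10)
  s_high <- nom$survival_at(100, 10)
  expect_gt(s_low, s_high)
  expect_gt(nom$survival_at(50, 5), nom$survival_at(50, 15))
})

test_that("SIR follows the hand arithmetic and scales inversely with rates", {
  rate_tab <- tibble::tibble(age_group = c("a", "b"), rate = c(0.001, 0.002))
  py_tab <- tibble::tibble(age_group = c("a", "b"), person_years = c(1000, 500))
  res <- sir(4, rate_tab, py_tab)
  expect_equal(unname(res["expected"]), 2)
  expect_equal(unname(res["sir"]), 2)
  doubled <- dplyr::mutate(rate_tab, rate = rate * 2)
  expect_equal(unname(sir(4, doubled, py_tab)["sir"]), 1)
  expect_error(sir(3, dplyr::mutate(rate_tab, rate = 0), py_tab),
               class = "hmcprog_config_error")
})

test_that("SIR is centred at 1 when the cohort follows the reference rates", {
  set.seed(74)
  rate <- c(a = 0.002, b = 0.006)
  sirs <- replicate(200, {
    n <- 1500
    stratum <- sample(names(rate), n, TRUE)
    t_event <- rexp(n, rate[stratum])
    time <- pmin(t_event, 10)
    obs <- sum(t_event <= 10)
    py <- tibble::tibble(age_group = names(rate),
                         person_years = vapply(names(rate), function(s)
                           sum(time[stratum == s]), numeric(1)))
    rt <- tibble::tibble(age_group = names(rate), rate = unname(rate))
    unname(sir(obs, rt, py)["sir"])
  })
  expect_lt(abs(mean(sirs) - 1), 3 * sd(sirs) / sqrt(length(sirs)))
})

test_that("2x2 chi-square matches the closed form and the expected-count oracle", {
  expect_equal(unname(chi2_2x2(matrix(c(10, 10, 10, 10), 2))["statistic"]), 0)
  expect_equal(unname(chi2_2x2(matrix(c(10, 10, 10, 10), 2))["p_value"]), 1)
  tab <- matrix(c(20, 10, 10, 20), 2)
  expect_equal(unname(chi2_2x2(tab)["statistic"]), 60 * (400 - 100)^2 / 30^4,
               tolerance = 1e-12)
  set.seed(75)
  for (i in 1:20) {
    tab <- matrix(sample(5:50, 4), 2)
    expect_equal(unname(chi2_2x2(tab)["statistic"]), oracle_chi2_2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("two-sample power hits the standard benchmarks", {
  expect_equal(power_two_sample(30, 30, 0, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(power_two_sample(64, 64, 0.5, 0.05), 0.80, tolerance = 0.01)
  ref <- power.t.test(n = 64, delta = 0.5, sd = 1)$power
  expect_equal(power_two_sample(64, 64, 0.5), ref, tolerance = 1e-5)
  # monotone in d and in min(n1, n2)
  expect_gt(power_two_sample(30, 30, 0.8), power_two_sample(30, 30, 0.4))
  expect_gt(power_two_sample(60, 30, 0.5), power_two_sample(30, 30, 0.5))
})

test_that("cohort summary handles empty strata and percentage partitions", {
  co <- make_fixture("table12_cohort")
  s <- cohort_summary(co)
  comp <- s$composition
  # percentages partition each lesion column (gender sums to 100)
  gsum <- comp |>
    dplyr::filter(.data$variable == "gender") |>
    dplyr::group_by(.data$lesion) |>
    dplyr::summarise(total = sum(.data$pct))
  expect_true(all(abs(gsum$total - 100) < 0.02))
  # empty stratum: a lesion group with no events of some gender
  co2 <- tibble::tibble(lesion = c("a", "a", "b"),
                        gender = c("male", "male", "female"),
                        age_group = "<50", time = c(2, 3, 4),
                        event = c(0L, 0L, 0L))
  s2 <- cohort_summary(co2)
  zero <- s2$composition[s2$composition$lesion == "a" &
                           s2$composition$level == "female", ]
  expect_equal(zero$n, 0L)
  expect_equal(zero$pct, 0)
})
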