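# Cohort epidemiology: descriptive tables, person-years, Kaplan-Meier
# cumulative incidence, Cox proportional hazards, nomogram point scaling,
# standardized incidence ratios, 2x2 chi-square and two-sample power.

check_cohort <- function(cohort) {
  need <- c("lesion", "gender", "age_group", "time", "event")
  stopifnot_config(is.data.frame(cohort) && all(need %in% names(cohort)),
                   paste("cohort needs columns:", paste(need, collapse = ", ")))
  stopifnot_config(all(cohort$time > 0), "follow-up times must be positive")
  stopifnot_config(all(cohort$event %in% c(0, 1)), "`event` must be 0/1")
  cohort
}

pct <- function(n, total) {
  if (total <= 0) return(rep(0, length(n)))
  round_half_up(100 * n / total, 2)
}

#' Descriptive cohort summary tables
#'
#' Reproduces the layout of baseline-characteristics and follow-up-outcome
#' tables: counts and percentages by lesion type for gender, age group and
#' biopsy location; gastric-adenocarcinoma outcome splits (total, within
#' the first year of the index endoscopy, after the first year); event
#' counts by gender and — when an `age_group_dx` column carries age at
#' diagnosis — by age at diagnosis; and medians/IQRs of times to
#' diagnosis. Percentages are of the lesion-group column total (or the
#' whole cohort for the `overall` column), rounded half-up to 2 decimals.
#' The first-year boundary is `time <= 1`.
#'
#' @param cohort Cohort tibble: `lesion`, `gender`, `age_group`, `time`
#'   (years), `event` (0/1), optionally `location`, `age_group_dx`.
#' @return List of class `hmc_cohort_summary` with tibbles `composition`,
#'   `outcomes`, `event_gender`, `event_age_dx` (if available),
#'   `time_to_event`.
#' @export
cohort_summary <- function(cohort) {
  cohort <- check_cohort(cohort)
  cohort$lesion <- as.character(cohort$lesion)
  groups <- c(unique(cohort$lesion), "overall")
  group_n <- c(table(cohort$lesion)[unique(cohort$lesion)],
               overall = nrow(cohort))

  one_var <- function(var) {
    if (!var %in% names(cohort)) return(NULL)
    purrr::map_dfr(groups, function(g) {
      sub <- if (g == "overall") cohort else cohort[cohort$lesion == g, ]
      tab <- table(as.character(sub[[var]]))
      lv <- sort(unique(as.character(cohort[[var]])))
      tibble(lesion = g, variable = var, level = lv,
             n = as.integer(tab[lv] %0% 0),
             pct = pct(as.integer(tab[lv] %0% 0), group_n[[g]]))
    })
  }
  composition <- dplyr::bind_rows(one_var("gender"), one_var("age_group"),
                                  one_var("location"))

  outcome_row <- function(g) {
    sub <- if (g == "overall") cohort else cohort[cohort$lesion == g, ]
    ev <- sub$event == 1
    first <- ev & sub$time <= 1
    tibble(lesion = g,
           n = nrow(sub),
           gac_total = sum(ev), gac_total_pct = pct(sum(ev), nrow(sub)),
           gac_first_year = sum(first),
           gac_first_year_pct = pct(sum(first), nrow(sub)),
           gac_after_first_year = sum(ev & !first),
           gac_after_first_year_pct = pct(sum(ev & !first), nrow(sub)))
  }
  outcomes <- purrr::map_dfr(groups, outcome_row)

  event_split <- function(var) {
    if (!var %in% names(cohort)) return(NULL)
    ev <- cohort[cohort$event == 1, ]
    purrr::map_dfr(setdiff(groups, "overall"), function(g) {
      sub <- ev[ev$lesion == g, ]
      lv <- sort(unique(as.character(cohort[[var]][cohort$event == 1])))
      tab <- table(as.character(sub[[var]]))
      tibble(lesion = g, level = lv, n = as.integer(tab[lv] %0% 0),
             pct = pct(as.integer(tab[lv] %0% 0), group_n[[g]]))
    })
  }
  event_gender <- event_split("gender")
  event_age_dx <- event_split("age_group_dx")

  tte <- purrr::map_dfr(setdiff(groups, "overall"), function(g) {
    ev <- cohort[cohort$lesion == g & cohort$event == 1, ]
    after <- ev$time[ev$time > 1]
    tibble(lesion = g,
           median_all = round_half_up(median(ev$time), 2),
           q1_all = round_half_up(unname(quantile(ev$time, 0.25)), 2),
           q3_all = round_half_up(unname(quantile(ev$time, 0.75)), 2),
           median_after_first_year = round_half_up(median(after), 2))
  })

  structure(list(composition = composition, outcomes = outcomes,
                 event_gender = event_gender, event_age_dx = event_age_dx,
                 time_to_event = tte),
            class = "hmc_cohort_summary")
}

`%0%` <- function(x, default) ifelse(is.na(x), default, x)

#' @export
print.hmc_cohort_summary <- function(x, ...) {
  cat("<hmc_cohort_summary>\n")
  print(x$outcomes)
  invisible(x)
}

#' Person-years and incidence rate
#'
#' Total (optionally stratified) follow-up time and the event rate per
#' 1000 person-years.
#'
#' @param cohort Cohort tibble with `time` and `event`.
#' @param by Optional grouping column names.
#' @return Tibble: grouping columns (if any), `person_years`, `events`,
#'   `rate_per_1000py`.
#' @export
person_years <- function(cohort, by = NULL) {
  cohort <- check_cohort(cohort)
  grouped <- if (is.null(by)) cohort else
    dplyr::group_by(cohort, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(grouped,
                   person_years = sum(.data$time),
                   events = sum(.data$event),
                   rate_per_1000py = ifelse(sum(.data$time) > 0,
                                            1000 * sum(.data$event) / sum(.data$time), 0),
                   .groups = "drop")
}

#' Kaplan-Meier cumulative incidence
#'
#' Product-limit estimate of cumulative incidence (`1 - S(t)`), optionally
#' by group; censored subjects leave the risk set without a step.
#'
#' @param cohort Cohort tibble with `time`, `event` and optional grouping
#'   column.
#' @param by Optional grouping column name.
#' @return Tibble of class `hmc_km`: `group` (if any), `time`, `n_risk`,
#'   `n_event`, `survival`, `cum_incidence`.
#' @export
km_cumulative_incidence <- function(cohort, by = NULL) {
  cohort <- check_cohort(cohort)
  form <- if (is.null(by)) survival::Surv(time, event) ~ 1 else
    stats::as.formula(paste("survival::Surv(time, event) ~", by))
  fit <- survival::survfit(form, data = cohort)
  strata <- if (is.null(by) || is.null(fit$strata)) {
    rep(if (is.null(by)) "all" else as.character(cohort[[by]][1]),
        length(fit$time))
  } else {
    rep(sub("^[^=]*=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, survival = fit$surv,
                cum_incidence = 1 - fit$surv)
  class(out) <- c("hmc_km", class(out))
  out
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Newton-Raphson, Breslow tie handling) of the
#' progression hazard on cohort covariates, reporting hazard ratios with
#' Wald 95% confidence intervals `exp(beta +/- 1.96 se)`.
#'
#' @param cohort Cohort tibble.
#' @param covariates Covariate column names (default lesion, gender,
#'   age_group).
#' @return Object of class `hmc_cox_fit` wrapping the `coxph` fit; use
#'   [tidy()] for the coefficient table.
#' @export
cox_ph_fit <- function(cohort, covariates = c("lesion", "gender", "age_group")) {
  cohort <- check_cohort(cohort)
  stopifnot_config(sum(cohort$event) >= 1, "need at least one event")
  stopifnot_config(all(covariates %in% names(cohort)),
                   "unknown covariate column(s)")
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = cohort, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 25)),
    warning = function(w) {
      if (grepl("iterations|infinite|converge", conditionMessage(w))) {
        abort(paste0("Cox fit did not converge (monotone likelihood?): ",
                     conditionMessage(w)),
              class = "hmcprog_fit_error")
      }
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(coef(fit)))) {
    abort("Cox fit did not converge (monotone likelihood?)",
          class = "hmcprog_fit_error")
  }
  structure(list(fit = fit, covariates = covariates, data = cohort),
            class = "hmc_cox_fit")
}

#' @export
tidy.hmc_cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(term = rownames(co),
         estimate = co[, "coef"],
         std_error = co[, "se(coef)"],
         hr = exp(co[, "coef"]),
         conf_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
         conf_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
         p_value = co[, "Pr(>|z|)"])
}

#' @export
glance.hmc_cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = s$n, n_event = s$nevent,
         concordance = unname(s$concordance["C"]),
         logtest_p = unname(s$logtest["pvalue"]))
}

#' @export
print.hmc_cox_fit <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Nomogram point scaling for a Cox fit
#'
#' Rescales each covariate's effect to the conventional 0-100 point scale:
#' the level of the covariate with the largest effect range scores 100 and
#' every reference (lowest-risk) level scores 0; a total-points-to-linear-
#' predictor mapping and survival probabilities at requested horizons
#' (from the Breslow baseline cumulative hazard) are attached.
#'
#' @param fit An [cox_ph_fit()] object.
#' @param horizons Years at which to report survival for a given total
#'   point count (default `c(5, 10, 20)`).
#' @return List of class `hmc_nomogram`: `points` tibble (`term`, `level`,
#'   `points`), `points_per_lp` (points per unit log hazard),
#'   `survival_at` function `(total_points, horizon)`.
#' @export
nomogram_points <- function(fit, horizons = c(5, 10, 20)) {
  stopifnot_config(inherits(fit, "hmc_cox_fit"), "`fit` must be an hmc_cox_fit")
  beta <- coef(fit$fit)
  # group coefficients by covariate; reference level has implicit beta 0
  terms <- lapply(fit$covariates, function(v) {
    lv <- levels(as.factor(fit$data[[v]]))
    b <- setNames(numeric(length(lv)), lv)
    for (l in lv) {
      nm <- paste0(v, l)
      if (nm %in% names(beta)) b[l] <- beta[nm]
    }
    b - min(b) # lowest-risk level = 0 points
  })
  names(terms) <- fit$covariates
  ranges <- vapply(terms, function(b) diff(range(b)), numeric(1))
  stopifnot_config(max(ranges) > 0, "all covariate effects are zero")
  scale_pts <- 100 / max(ranges)
  points <- purrr::map_dfr(fit$covariates, function(v) {
    tibble(term = v, level = names(terms[[v]]),
           points = unname(terms[[v]] * scale_pts))
  })
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  lp_offset <- sum(vapply(terms, min, numeric(1))) # zero by construction
  survival_at <- function(total_points, horizon) {
    lp <- total_points / scale_pts + lp_offset
    h0 <- if (any(bh$time <= horizon)) max(bh$hazard[bh$time <= horizon]) else 0
    exp(-h0 * exp(lp))
  }
  structure(list(points = points, points_per_lp = scale_pts,
                 survival_at = survival_at, horizons = horizons),
            class = "hmc_nomogram")
}

#' Standardized incidence ratio
#'
#' Observed events divided by the expected count under stratum-specific
#' reference rates: `expected = sum(rate * person_years)` over strata.
#'
#' @param observed Observed event count.
#' @param rate_table Tibble with stratum columns plus `rate` (events per
#'   person-year).
#' @param py_table Tibble with the same stratum columns plus
#'   `person_years`.
#' @return Named numeric: `observed`, `expected`, `sir`.
#' @export
sir <- function(observed, rate_table, py_table) {
  stopifnot_config(is_count(observed), "`observed` must be a count")
  stopifnot_config("rate" %in% names(rate_table) &&
                     "person_years" %in% names(py_table),
                   "rate_table needs `rate`; py_table needs `person_years`")
  strata <- setdiff(intersect(names(rate_table), names(py_table)),
                    c("rate", "person_years"))
  stopifnot_config(length(strata) >= 1, "no shared stratum columns")
  joined <- dplyr::inner_join(py_table, rate_table, by = strata)
  stopifnot_config(nrow(joined) == nrow(py_table),
                   "rate table does not cover every cohort stratum")
  expected <- sum(joined$rate * joined$person_years)
  if (expected == 0 && observed > 0) {
    abort("expected count is zero with positive observed events",
          class = "hmcprog_config_error")
  }
  c(observed = observed, expected = expected,
    sir = if (expected > 0) observed / expected else NA_real_)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default (Yates optional), p-value from
#' the 1-df chi-square distribution.
#'
#' @param tab 2x2 matrix of counts.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return Named numeric `statistic`, `p_value`.
#' @export
chi2_2x2 <- function(tab, correct = FALSE) {
  stopifnot_config(is.matrix(tab) && all(dim(tab) == c(2, 2)) && all(tab >= 0),
                   "`tab` must be a non-negative 2x2 matrix")
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  c(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution with noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))` for standardized effect size `d`.
#'
#' @param n1,n2 Group sizes.
#' @param effect_size_d Standardized mean difference (Cohen's d).
#' @param alpha Two-sided type-I error (default 0.05).
#' @return Power in [alpha, 1].
#' @export
power_two_sample <- function(n1, n2, effect_size_d, alpha = 0.05) {
  stopifnot_config(is_count(n1) && is_count(n2) && n1 >= 2 && n2 >= 2,
                   "group sizes must be counts >= 2")
  df <- n1 + n2 - 2
  ncp <- effect_size_d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp = ncp) + pt(-tc, df, ncp = ncp)
}
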