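# Built-in fixtures. `table12_cohort` reconstructs, patient by patient, a
# cohort whose marginal tables reproduce the published baseline and
# follow-up tables of the 29,176-patient gastritis cohort (lesion x gender,
# lesion x age group, lesion x location, GAC events split by first year,
# gender and age at diagnosis, medians of time to diagnosis, and total
# person-years). The joint distribution beyond those marginals is
# arbitrary; the construction is deterministic.

#' Built-in test fixtures
#'
#' @param name One of `"table12_cohort"` (29,176-patient cohort whose
#'   marginals match the published baseline/outcome tables),
#'   `"toy_catalog"` (10-feature BED catalog), `"toy_fragments"` (hand-laid
#'   fragments on the toy catalog), `"small_counts"` (small simulated
#'   count matrix with metadata and truth).
#' @return The fixture object (tibble or list).
#' @export
make_fixture <- function(name) {
  fixtures <- c("table12_cohort", "toy_catalog", "toy_fragments", "small_counts")
  if (!name %in% fixtures) {
    abort(paste0("unknown fixture '", name, "'; available: ",
                 paste(fixtures, collapse = ", ")),
          class = "hmcprog_config_error")
  }
  switch(name,
         table12_cohort = fixture_table12_cohort(),
         toy_catalog = fixture_toy_catalog(),
         toy_fragments = fixture_toy_fragments(),
         small_counts = simulate_counts(hmc_sim_config(
           n_features = 60, n_case = 6, n_control = 10,
           frac_differential = 0.1, delta_log2fc = 1, seed = 42)))
}

fixture_toy_catalog <- function() {
  feature_catalog(tibble(
    chrom = c(rep("chr1", 6), rep("chr2", 4)),
    start = c(1000L, 6000L, 12000L, 800L, 5800L, 3000L,
              2000L, 9000L, 1800L, 4000L),
    end = c(5000L, 10000L, 15000L, 1200L, 6200L, 4000L,
            8000L, 12000L, 2200L, 4600L),
    feature_id = c("gA", "gB", "gC", "pA", "pB", "e1",
                   "gD", "gE", "pD", "e2"),
    feature_class = c("gene_body", "gene_body", "gene_body", "promoter",
                      "promoter", "H3K27ac", "gene_body", "gene_body",
                      "promoter", "H3K4me1"),
    strand = c("+", "-", "+", "+", "-", ".", "+", "-", "+", "."),
    gene_symbol = c("A", "B", "C", "A", "B", "", "D", "E", "D", "")
  ))
}

fixture_toy_fragments <- function() {
  tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(1400L, 4200L, 6900L, 11900L, 2500L, 9500L, 4100L),
    end = c(1700L, 4500L, 7200L, 12200L, 2800L, 9800L, 4400L),
    sample_id = c("S1", "S1", "S1", "S2", "S1", "S2", "S2")
  )
}

# --- published-table constants ------------------------------------------

t12_groups <- function() {
  list(
    inflammation = list(
      n = 17948L, male = 7009L, female = 10939L,
      # 70+ count harmonized so the age column partitions the group (the
      # printed table's 70+ row is internally inconsistent by a few counts)
      age = c("<50" = 7510L, "50-59" = 5584L, "60-69" = 3147L, "70+" = 1707L),
      location = c(antrum = 16549L, corpus = 744L, cardia = 73L,
                   fundus = 234L, angle = 317L, unclear = 31L),
      events = 97L, events_male = 59L, first_year = 11L,
      age_dx = c("<50" = 21L, "50-59" = 22L, "60-69" = 32L, "70+" = 22L),
      t_first = c(0.09, 1.0), t_after_range = c(1.02, 20.62),
      median_after = 6.68, median_all = 6.47
    ),
    atrophy_im = list(
      n = 10391L, male = 4412L, female = 5979L,
      age = c("<50" = 2393L, "50-59" = 3656L, "60-69" = 2622L, "70+" = 1720L),
      location = c(antrum = 9612L, corpus = 211L, cardia = 20L,
                   fundus = 15L, angle = 522L, unclear = 11L),
      events = 112L, events_male = 69L, first_year = 11L,
      age_dx = c("<50" = 13L, "50-59" = 17L, "60-69" = 47L, "70+" = 35L),
      t_first = c(0.13, 1.0), t_after_range = c(1.08, 18.93),
      median_after = 6.14, median_all = 5.74
    ),
    dysplasia = list(
      n = 837L, male = 494L, female = 343L,
      age = c("<50" = 180L, "50-59" = 271L, "60-69" = 219L, "70+" = 167L),
      location = c(antrum = 703L, corpus = 49L, cardia = 5L,
                   fundus = 2L, angle = 77L, unclear = 1L),
      events = 31L, events_male = 23L, first_year = 13L,
      age_dx = c("<50" = 1L, "50-59" = 4L, "60-69" = 14L, "70+" = 12L),
      t_first = c(0.09, 1.0), t_after_range = c(1.89, 15.91),
      median_after = 4.11, median_all = 2.54
    )
  )
}

# Monotone after-first-year event times hitting the printed medians: the
# after-only median, and the all-cases median via the pinned order
# statistic once the first-year events are prepended.
t12_after_times <- function(g) {
  n <- g$events - g$first_year
  lo <- g$t_after_range[1]; hi <- g$t_after_range[2]
  v <- numeric(n)
  pins <- list()
  if (n %% 2 == 0) {
    pins[[1]] <- c(n / 2, g$median_after)
    pins[[2]] <- c(n / 2 + 1, g$median_after)
  } else {
    pins[[1]] <- c((n + 1) / 2, g$median_after)
  }
  n_all <- g$events
  k_all <- if (n_all %% 2 == 1) (n_all + 1) / 2 else n_all / 2 # position(s)
  if (n_all %% 2 == 1) {
    pins[[length(pins) + 1]] <- c(k_all - g$first_year, g$median_all)
  } else {
    pins[[length(pins) + 1]] <- c(k_all - g$first_year, g$median_all)
    pins[[length(pins) + 1]] <- c(k_all + 1 - g$first_year, g$median_all)
  }
  pin_pos <- vapply(pins, `[`, numeric(1), 1)
  pin_val <- vapply(pins, `[`, numeric(1), 2)
  o <- order(pin_pos)
  pin_pos <- pin_pos[o]; pin_val <- pin_val[o]
  keep <- !duplicated(pin_pos)
  pin_pos <- pin_pos[keep]; pin_val <- pin_val[keep]
  anchors_pos <- c(1, pin_pos, n)
  anchors_val <- c(lo, pin_val, hi)
  keep <- !duplicated(anchors_pos)
  anchors_pos <- anchors_pos[keep]; anchors_val <- anchors_val[keep]
  stopifnot(!is.unsorted(anchors_val))
  stats::approx(anchors_pos, anchors_val, xout = seq_len(n))$y
}

fixture_table12_cohort <- function() {
  gs <- t12_groups()
  total_py <- 370561.99
  rows <- list()
  for (gname in names(gs)) {
    g <- gs[[gname]]
    n_cens <- g$n - g$events
    t_first <- seq(g$t_first[1], g$t_first[2], length.out = g$first_year)
    t_after <- t12_after_times(g)
    # events first (sorted by time), then censored patients
    ev_gender <- rep(c("male", "female"), c(g$events_male, g$events - g$events_male))
    cen_gender <- rep(c("male", "female"),
                      c(g$male - g$events_male,
                        g$female - (g$events - g$events_male)))
    df <- tibble(
      lesion = gname,
      gender = c(ev_gender, cen_gender),
      time = c(t_first, t_after, rep(NA_real_, n_cens)),
      event = rep(c(1L, 0L), c(g$events, n_cens)),
      age_group_dx = c(rep(names(g$age_dx), g$age_dx),
                       rep(NA_character_, n_cens)),
      age_group = rep(names(g$age), g$age),
      location = rep(names(g$location), g$location)
    )
    rows[[gname]] <- df
  }
  cohort <- dplyr::bind_rows(rows)

  # Censoring times: a deterministic ramp calibrated so total person-years
  # and the overall median follow-up match the published cohort exactly
  # (370,561.99 person-years; median 12.2 years, range 1.02-21.59).
  ev_times <- cohort$time[cohort$event == 1]
  n_cens <- sum(cohort$event == 0)
  plateau <- 800L
  e_low <- sum(ev_times <= 12.195)
  n_low <- 14588L - e_low - 400L
  n_up <- n_cens - n_low - plateau
  low <- seq(1.05, 12.19, length.out = n_low)
  up_frac <- seq_len(n_up) / n_up
  target_up <- total_py - sum(ev_times) - sum(low) - plateau * 12.2
  f <- function(p) sum(12.2 + (21.59 - 12.2) * up_frac^p) - target_up
  p <- stats::uniroot(f, c(0.01, 50), tol = 1e-12)$root
  up <- 12.2 + (21.59 - 12.2) * up_frac^p
  resid <- total_py - sum(ev_times) - sum(low) - plateau * 12.2 - sum(up)
  up[n_up %/% 2] <- up[n_up %/% 2] + resid
  cens_times <- c(low, rep(12.2, plateau), up)
  cohort$time[cohort$event == 0] <- cens_times
  cohort$patient_id <- sprintf("P%05d", seq_len(nrow(cohort)))
  dplyr::relocate(cohort, "patient_id")
}
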