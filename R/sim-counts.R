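#' Configuration for the 5hmC-Seal count simulator
#'
#' Defines the generative model used by [simulate_counts()]: negative-binomial
#' fragment counts over genomic features (gene bodies at desk scale), with a
#' planted case-vs-control log2 fold change on a fraction of features,
#' per-sample library-size factors and optional multiplicative batch effects.
#' Defaults emulate the study conditions of the motivating cohort: 21
#' progression cases versus 48 non-progressed controls, planted effects with
#' |log2FC| between 0.26 (a 20% fold change) and 1, and an overdispersion
#' typical of 5hmC-Seal gene-body counts.
#'
#' @param n_features Number of features (gene bodies) to simulate.
#' @param n_case,n_control Sample sizes of the progression and control groups.
#' @param frac_differential Fraction of features carrying a planted effect.
#' @param delta_log2fc Magnitude of the planted log2 fold change: either a
#'   single value or a length-2 range to draw magnitudes from uniformly.
#'   Signs are assigned at random (hyper- vs hypo-hydroxymethylated).
#' @param baseline_log_mean_range Range (natural-log scale) of per-feature
#'   baseline mean counts.
#' @param dispersion Negative-binomial dispersion `phi` with
#'   `variance = mu + phi * mu^2`; `phi = 0` gives Poisson counts.
#' @param size_factor_range Range of per-sample library scale factors, drawn
#'   log-uniformly.
#' @param n_batches Number of processing batches; samples are assigned round
#'   robin within each group so batch is orthogonal to case status.
#' @param batch_log2_shift Per-batch additive shift on the log2 scale: a
#'   vector of length `n_batches`, or a single spacing from which centred
#'   shifts are built.
#' @param seed Integer seed; output is deterministic given the config.
#' @return A list of class `hmc_sim_config`.
#' @seealso [simulate_counts()]
#' @export
hmc_sim_config <- function(n_features = 2000,
                           n_case = 21,
                           n_control = 48,
                           frac_differential = 0.05,
                           delta_log2fc = c(0.26, 1),
                           baseline_log_mean_range = c(log(20), log(2000)),
                           dispersion = 0.2,
                           size_factor_range = c(0.5, 2),
                           n_batches = 1,
                           batch_log2_shift = 0.5,
                           seed = 1L) {
  stopifnot_config(is_count(n_features) && n_features >= 1, "`n_features` must be a positive count.")
  stopifnot_config(is_count(n_case) && n_case > 0, "`n_case` must be > 0.")
  stopifnot_config(is_count(n_control) && n_control > 0, "`n_control` must be > 0.")
  stopifnot_config(is.numeric(frac_differential) && frac_differential >= 0 &&
                     frac_differential <= 1, "`frac_differential` must be in [0, 1].")
  stopifnot_config(is.numeric(delta_log2fc) && length(delta_log2fc) %in% 1:2 &&
                     all(delta_log2fc >= 0), "`delta_log2fc` must be a non-negative value or range.")
  stopifnot_config(is.numeric(baseline_log_mean_range) && length(baseline_log_mean_range) == 2 &&
                     diff(baseline_log_mean_range) >= 0, "`baseline_log_mean_range` must be an increasing interval.")
  stopifnot_config(is.numeric(dispersion) && dispersion >= 0, "`dispersion` must be >= 0.")
  stopifnot_config(is.numeric(size_factor_range) && length(size_factor_range) == 2 &&
                     all(size_factor_range > 0) && diff(size_factor_range) >= 0,
                   "`size_factor_range` must be a positive increasing interval.")
  stopifnot_config(is_count(n_batches) && n_batches >= 1, "`n_batches` must be >= 1.")
  stopifnot_config(is.numeric(batch_log2_shift) &&
                     length(batch_log2_shift) %in% c(1L, as.integer(n_batches)),
                   "`batch_log2_shift` must be a single spacing or one shift per batch.")
  structure(
    list(n_features = as.integer(n_features), n_case = as.integer(n_case),
         n_control = as.integer(n_control), frac_differential = frac_differential,
         delta_log2fc = delta_log2fc,
         baseline_log_mean_range = baseline_log_mean_range,
         dispersion = dispersion, size_factor_range = size_factor_range,
         n_batches = as.integer(n_batches), batch_log2_shift = batch_log2_shift,
         seed = as.integer(seed)),
    class = "hmc_sim_config"
  )
}

batch_shifts <- function(config) {
  b <- config$n_batches
  if (b == 1L) {
    shifts <- 0
  } else if (length(config$batch_log2_shift) == b) {
    shifts <- config$batch_log2_shift
  } else {
    shifts <- (seq_len(b) - (b + 1) / 2) * config$batch_log2_shift
  }
  names(shifts) <- paste0("batch", seq_len(b))
  shifts
}

#' Simulate a 5hmC-Seal count matrix with known ground truth
#'
#' Draws a feature-by-sample table of negative-binomial counts under the
#' model `mu[g, s] = sf[s] * b[g] * 2^(delta[g] * case[s]) * 2^(shift[batch[s]])`
#' with `variance = mu + phi * mu^2`, together with per-sample metadata
#' (case/control status, age, gender, lesion type, batch) and a truth record
#' of every planted parameter, so that downstream normalization,
#' batch-adjustment, differential and selection stages can be tested against
#' a known answer.
#'
#' @param config An [hmc_sim_config()].
#' @return A list of class `hmc_sim` with elements
#'   \describe{
#'     \item{counts}{tibble, `feature_id` plus one integer column per sample.}
#'     \item{samples}{tibble of per-sample metadata (`sample_id`, `group`,
#'       `age`, `gender`, `lesion`, `batch`).}
#'     \item{truth}{list: `differential_feature_ids`, per-feature
#'       `log2fc` tibble, `size_factors`, `batch_log2_shifts`.}
#'   }
#' @examples
#' sim <- simulate_counts(hmc_sim_config(n_features = 50, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  stopifnot_config(inherits(config, "hmc_sim_config"),
                   "`config` must be created by hmc_sim_config().")
  n <- config$n_case + config$n_control
  g <- config$n_features
  with_seed(config$seed, {
    feature_id <- sprintf("gene_%05d", seq_len(g))
    sample_id <- sprintf("S%03d", seq_len(n))
    group <- rep(c("case", "control"), c(config$n_case, config$n_control))

    # Batch assigned round robin within each group: orthogonal to status.
    batch <- integer(n)
    for (grp in c("case", "control")) {
      idx <- which(group == grp)
      batch[idx] <- rep_len(seq_len(config$n_batches), length(idx))
    }
    shifts <- batch_shifts(config)

    n_diff <- round(config$frac_differential * g)
    diff_idx <- if (n_diff > 0) sort(sample.int(g, n_diff)) else integer(0)
    mag <- if (length(config$delta_log2fc) == 2) {
      runif(n_diff, config$delta_log2fc[1], config$delta_log2fc[2])
    } else {
      rep(config$delta_log2fc, n_diff)
    }
    delta <- numeric(g)
    delta[diff_idx] <- mag * sample(c(-1, 1), n_diff, replace = TRUE)

    b_g <- exp(runif(g, config$baseline_log_mean_range[1],
                     config$baseline_log_mean_range[2]))
    sf <- exp(runif(n, log(config$size_factor_range[1]),
                    log(config$size_factor_range[2])))

    mu <- outer(b_g, sf) * 2^(outer(delta, as.numeric(group == "case"))) *
      2^(matrix(shifts[batch], nrow = g, ncol = n, byrow = TRUE))
    counts <- if (config$dispersion > 0) {
      matrix(rnbinom(g * n, size = 1 / config$dispersion, mu = mu), nrow = g)
    } else {
      matrix(rpois(g * n, lambda = mu), nrow = g)
    }
    dimnames(counts) <- list(feature_id, sample_id)

    # Clinical metadata mirroring the profiled subset's composition:
    # age/gender approximately matched between groups, lesion mix close to
    # the 32/26/11 inflammation : atrophy/IM : dysplasia split.
    age <- round(runif(n, 45, 80))
    gender <- sample(c("male", "female"), n, replace = TRUE)
    lesion <- sample(c("inflammation", "atrophy_im", "dysplasia"), n,
                     replace = TRUE, prob = c(32, 26, 11) / 69)

    samples <- tibble(sample_id = sample_id, group = group, age = age,
                      gender = gender, lesion = lesion,
                      batch = paste0("batch", batch))
    truth <- list(
      differential_feature_ids = feature_id[diff_idx],
      log2fc = tibble(feature_id = feature_id, true_log2fc = delta),
      size_factors = setNames(sf, sample_id),
      batch_log2_shifts = shifts,
      baseline_mean = setNames(b_g, feature_id)
    )
    structure(list(counts = as_feature_tibble(counts), samples = samples,
                   truth = truth, config = config),
              class = "hmc_sim")
  })
}

#' @export
print.hmc_sim <- function(x, ...) {
  cat("<hmc_sim> ", nrow(x$counts), " features x ", nrow(x$samples),
      " samples (", sum(x$samples$group == "case"), " case / ",
      sum(x$samples$group == "control"), " control), ",
      length(x$truth$differential_feature_ids), " planted differential\n",
      sep = "")
  invisible(x)
}
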