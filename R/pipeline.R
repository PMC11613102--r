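# Orchestration of the full analysis: simulate (or load) counts ->
# normalize (+ batch adjust) -> differential + covariate screen ->
# stability selection -> risk model. One master seed is fanned out per
# stage by stable hashing of the stage name, so each stage is individually
# reproducible.

#' Pipeline configuration
#'
#' @param sim An [hmc_sim_config()] for the simulation stage (or `NULL`
#'   when `counts`/`samples` are supplied directly to [run_pipeline()]).
#' @param pseudocount Pseudocount for normalization and fold changes.
#' @param combat Run empirical-Bayes batch adjustment when more than one
#'   batch is present (default TRUE).
#' @param lfc_min,p_max Differential call thresholds (volcano rule).
#' @param screen_p Covariate-screen retention threshold (default 0.01).
#' @param selection A [selection_config()] for stability selection.
#' @param split_ratio Training fraction for the stratified split.
#' @param min_specificity Validation specificity floor for the cutoff.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "normalize", "diff", "select", "model")`.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = hmc_sim_config(),
                            pseudocount = 1,
                            combat = TRUE,
                            lfc_min = 0.26, p_max = 0.05,
                            screen_p = 0.01,
                            selection = selection_config(),
                            split_ratio = 2 / 3,
                            min_specificity = 0.90,
                            stages = c("simulate", "normalize", "diff",
                                       "select", "model"),
                            seed = 1L) {
  valid <- c("simulate", "normalize", "diff", "select", "model")
  stopifnot_config(all(stages %in% valid),
                   paste("stages must be among:", paste(valid, collapse = ", ")))
  structure(list(sim = sim, pseudocount = pseudocount, combat = combat,
                 lfc_min = lfc_min, p_max = p_max, screen_p = screen_p,
                 selection = selection, split_ratio = split_ratio,
                 min_specificity = min_specificity,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML file may contain top-level keys matching the arguments of
#' [pipeline_config()] (scalar settings, `stages` as a list) plus nested
#' `sim` and `selection` blocks with the arguments of [hmc_sim_config()]
#' and [selection_config()]. Unknown keys are errors, which protects
#' against silent typos.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
pipeline_config_from_yaml <- function(path) {
  stopifnot_config(file.exists(path), paste("no such file:", path))
  raw <- yaml::read_yaml(path)
  stopifnot_config(is.list(raw), "YAML config must be a mapping")
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    stopifnot_config(length(bad) == 0,
                     paste0("unknown ", where, " config key(s): ",
                            paste(bad, collapse = ", ")))
  }
  check_keys(raw, names(formals(pipeline_config)), "pipeline")
  args <- raw
  if (!is.null(raw$sim)) {
    check_keys(raw$sim, names(formals(hmc_sim_config)), "sim")
    args$sim <- do.call(hmc_sim_config, raw$sim)
  }
  if (!is.null(raw$selection)) {
    check_keys(raw$selection, names(formals(selection_config)), "selection")
    args$selection <- do.call(selection_config, raw$selection)
  }
  if (!is.null(raw$stages)) args$stages <- unlist(raw$stages)
  do.call(pipeline_config, args)
}

#' Run the progression-risk pipeline
#'
#' Executes the enabled stages in order and returns a run report with
#' per-stage record counts, the selected panel and the risk-model metrics.
#' Later stages refuse to run when an earlier stage they depend on was
#' disabled and its output not supplied.
#'
#' @param config A [pipeline_config()].
#' @param counts,samples Optional pre-computed inputs (used when the
#'   `simulate` stage is disabled).
#' @return List of class `hmc_run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), counts = NULL,
                         samples = NULL) {
  stopifnot_config(inherits(config, "pipeline_config"),
                   "`config` must come from pipeline_config()")
  stages <- config$stages
  report <- list(seed = config$seed, stages = stages, counts = list())
  t0 <- Sys.time()
  state <- list(counts = counts, samples = samples)

  log_stage <- function(stage, msg) {
    message(sprintf("[hmcprog] stage=%s seed=%d %s", stage, config$seed, msg))
  }

  if ("simulate" %in% stages) {
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_counts(cfg)
    state$counts <- sim$counts
    state$samples <- sim$samples
    state$truth <- sim$truth
    report$counts$features_simulated <- nrow(sim$counts)
    log_stage("simulate", paste(nrow(sim$counts), "features"))
  }
  stopifnot_config(!is.null(state$counts) && !is.null(state$samples),
                   "no counts available: enable the simulate stage or supply `counts` and `samples`")

  if ("normalize" %in% stages) {
    norm <- normalize_log(state$counts, pseudocount = config$pseudocount)
    if (config$combat && length(unique(state$samples$batch %||% "b")) > 1) {
      covs <- state$samples[intersect(c("group", "age", "gender"),
                                      names(state$samples))]
      norm <- combat_adjust(norm, state$samples$batch, covariates = covs)
    }
    state$norm <- norm
    report$counts$features_normalized <- nrow(norm$values)
    log_stage("normalize", "done")
  }

  if ("diff" %in% stages) {
    stopifnot_config(!is.null(state$norm),
                     "diff stage requires the normalize stage")
    diff <- differential_test(state$counts, state$samples$group,
                              pseudocount = config$pseudocount)
    diff <- call_differential(diff, config$lfc_min, config$p_max)
    screen <- covariate_screen(state$norm, state$samples$group,
                               state$samples$age, state$samples$gender,
                               p_threshold = config$screen_p)
    state$differential <- diff
    state$candidates <- screen$feature_id[screen$keep]
    report$counts$features_called <- sum(diff$direction != "ns")
    report$counts$candidates <- length(state$candidates)
    log_stage("diff", paste(report$counts$features_called, "called,",
                            report$counts$candidates, "candidates"))
  }

  if ("select" %in% stages || "model" %in% stages) {
    state$samples <- split_train_valid(state$samples, config$split_ratio,
                                       derive_seed(config$seed, "split"))
  }

  if ("select" %in% stages) {
    stopifnot_config(!is.null(state$candidates),
                     "select stage requires the diff stage (no candidate list)")
    stopifnot_config(length(state$candidates) >= 2,
                     "fewer than 2 screened candidates; nothing to select from")
    sel_cfg <- config$selection
    sel_cfg$seed <- derive_seed(config$seed, "select")
    tr <- state$samples$split == "train"
    m <- norm_values(state$norm)
    X <- t(m[state$candidates, state$samples$sample_id[tr], drop = FALSE])
    y <- as.integer(state$samples$group[tr] == "case")
    state$selection <- stability_select(X, y, sel_cfg)
    report$counts$panel <- length(state$selection$panel)
    report$panel <- state$selection$panel
    log_stage("select", paste("panel of", length(state$selection$panel)))
  }

  if ("model" %in% stages) {
    stopifnot_config(!is.null(state$norm), "model stage requires normalize")
    panel <- state$selection$panel %||% character(0)
    model <- fit_risk_model(state$norm, state$samples, panel,
                            min_specificity = config$min_specificity,
                            seed = derive_seed(config$seed, "model"))
    state$model <- model
    report$model <- list(
      train_auc = model$train_auc, validation_auc = model$validation_auc,
      cutoff = model$cutoff, sensitivity_all = model$sensitivity_all,
      specificity_all = model$specificity_all)
    log_stage("model", sprintf("validation AUC %.3f", model$validation_auc))
  }

  report$elapsed_s <- as.numeric(Sys.time() - t0, units = "secs")
  report$config_hash <- object_hash(config)
  report$state <- state
  class(report) <- "hmc_run_report"
  report
}

#' Stable content hash of a run report
#'
#' Hashes the reproducible parts of the report (counts, panel, model
#' metrics, seed and config hash), excluding wall-clock time, so two runs
#' with the same config and seed hash identically.
#'
#' @param report An `hmc_run_report`.
#' @return md5 string.
#' @export
run_report_hash <- function(report) {
  object_hash(report[c("seed", "stages", "counts", "panel", "model",
                       "config_hash")])
}

#' @export
print.hmc_run_report <- function(x, ...) {
  cat("<hmc_run_report> seed ", x$seed, ", stages: ",
      paste(x$stages, collapse = " -> "), "\n", sep = "")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  if (!is.null(x$model)) {
    cat("  validation AUC: ", round_half_up(100 * x$model$validation_auc, 1),
        "%\n", sep = "")
  }
  invisible(x)
}
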