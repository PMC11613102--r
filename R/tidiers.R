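# broom-style tidiers for fitted objects.

#' @export
tidy.hmc_selection <- function(x, ...) {
  dplyr::arrange(x$frequency, dplyr::desc(.data$frequency))
}

#' @export
glance.hmc_selection <- function(x, ...) {
  tibble(n_features = nrow(x$frequency),
         n_bootstrap = x$config$n_bootstrap,
         panel_size = length(x$panel),
         freq_min = x$config$freq_min,
         importance_min = x$config$importance_min)
}

#' @export
tidy.hmc_risk_model <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @export
glance.hmc_risk_model <- function(x, ...) {
  tibble(train_auc = x$train_auc,
         train_auc_low = x$train_auc_ci[["lower"]],
         train_auc_high = x$train_auc_ci[["upper"]],
         validation_auc = x$validation_auc,
         validation_auc_low = x$validation_auc_ci[["lower"]],
         validation_auc_high = x$validation_auc_ci[["upper"]],
         cutoff = x$cutoff,
         sensitivity_all = x$sensitivity_all,
         specificity_all = x$specificity_all,
         separation = x$separation)
}

#' @export
tidy.hmc_norm <- function(x, ...) {
  tidyr::pivot_longer(x$values, -"feature_id", names_to = "sample_id",
                      values_to = "log2_value")
}
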