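# ggplot2 autoplot methods for the package's result types.

#' Volcano plot of a differential table
#'
#' @param object An `hmc_differential` tibble (ideally after
#'   [call_differential()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hmc_differential <- function(object, ...) {
  df <- as_tibble(object)
  if (!"direction" %in% names(df)) df$direction <- "ns"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_empirical, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b", hypo = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case vs control)",
                  y = "-log10 empirical p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Metagene profile plot (TSS to TES with flanks)
#'
#' @param object An `hmc_metagene` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hmc_metagene <- function(object, ...) {
  lay <- attr(object, "layout")
  b1 <- lay$n_flank_bins + 0.5
  b2 <- lay$n_flank_bins + lay$n_body_bins + 0.5
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(b1, b2), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::annotate("text", x = c(b1, b2), y = Inf, label = c("TSS", "TES"),
                      vjust = 1.5, size = 3) +
    ggplot2::labs(x = "bin (upstream flank | scaled gene body | downstream flank)",
                  y = "mean fragment density (per kb per gene)") +
    ggplot2::theme_minimal()
}

#' Selection-frequency plot for stability selection
#'
#' @param object An `hmc_selection` object.
#' @param top Show the `top` most frequently selected features (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hmc_selection <- function(object, top = 30, ...) {
  df <- dplyr::slice_max(object$frequency, .data$frequency, n = top,
                         with_ties = FALSE)
  df$in_panel <- df$feature_id %in% object$panel
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature_id, .data$frequency),
                                   y = .data$frequency, fill = .data$in_panel)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$config$freq_min,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bootstrap selection frequency", fill = "panel") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object An `hmc_roc` object from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hmc_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.1f%%", 100 * object$auc)) +
    ggplot2::theme_minimal()
}

#' Cumulative-incidence (Kaplan-Meier) plot
#'
#' @param object An `hmc_km` tibble from [km_cumulative_incidence()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hmc_km <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$cum_incidence,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "years of follow-up", y = "cumulative incidence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
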