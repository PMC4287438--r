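# ggplot2 views of the result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line geom_smooth
#'   geom_errorbar geom_abline labs theme_minimal facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a decile table
#'
#' Decile means of a chosen metric (points and line) over the PWM-score
#' deciles, optionally with the spacer-frequency stacked bars underneath.
#'
#' @param object A `p53_decile_table`.
#' @param metric Column to plot (default `"mean_density"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.p53_decile_table <- function(object, metric = "mean_density", ...) {
  ggplot(object, aes(x = .data$decile, y = .data[[metric]], group = 1)) +
    geom_line(colour = "grey40") +
    geom_point(shape = 18, size = 3) +
    labs(x = "PWM score decile (weak → strong)", y = metric) +
    theme_minimal()
}

#' Spacer-frequency profile across deciles
#'
#' Stacked per-decile frequencies of spacer lengths 0-3.
#'
#' @param dec A `p53_decile_table`.
#' @return A ggplot object.
#' @export
plot_spacer_frequencies <- function(dec) {
  long <- dec |>
    select("decile", dplyr::starts_with("spacer_freq_")) |>
    tidyr::pivot_longer(-"decile", names_to = "spacer",
                        names_prefix = "spacer_freq_",
                        values_to = "frequency")
  ggplot(long, aes(x = .data$decile, y = .data$frequency,
                   fill = .data$spacer)) +
    geom_col() +
    labs(x = "PWM score decile", y = "frequency", fill = "spacer (nt)") +
    theme_minimal()
}

#' Plot a group-mean regression
#'
#' @param object A `p53_reg`.
#' @param ... Unused.
#' @return A ggplot of the group means with the fitted line.
#' @exportS3Method ggplot2::autoplot
autoplot.p53_reg <- function(object, ...) {
  d <- tibble(x = object$fit$model$x, y = object$fit$model$y)
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(size = 3) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "steelblue") +
    labs(subtitle = sprintf("slope = %.3g, r² = %.2f",
                            object$slope, object$r_squared)) +
    theme_minimal()
}

#' Per-state mean and SEM bars
#'
#' @param state_summary The `summary` element of
#'   [group_summaries_by_state()] (or of a `p53_summary`).
#' @param metric Metric to display.
#' @return A ggplot object.
#' @export
plot_state_summary <- function(state_summary, metric = "density") {
  d <- filter(state_summary, .data$metric == !!metric)
  ggplot(d, aes(x = factor(.data$state, levels = HMM7_STATES),
                y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.25) +
    labs(x = NULL, y = paste("mean", metric)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' TE-family enrichment plot
#'
#' Fold enrichment per family; families below the FDR threshold are
#' highlighted.
#'
#' @param te_enrichment Output of [te_family_enrichment()].
#' @param fdr Highlight threshold on `q_value`.
#' @return A ggplot object.
#' @export
plot_te_enrichment <- function(te_enrichment, fdr = 0.05) {
  d <- mutate(te_enrichment, significant = .data$q_value < fdr)
  ggplot(d, aes(x = stats::reorder(.data$family, -.data$fold),
                y = .data$fold, fill = .data$significant)) +
    geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    labs(x = NULL, y = "fold enrichment vs genome",
         fill = paste0("FDR < ", fdr)) +
    theme_minimal()
}
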