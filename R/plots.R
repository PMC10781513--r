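#' Plot a windowed recombination landscape
#'
#' Step plot of window rates along each chromosome, faceted by
#' chromosome — the standard way to eyeball telomeric elevation and
#' central deserts.
#'
#' @param windows Window table from [window_rates()].
#' @param log_y Use a log10 rate axis.
#' @return A ggplot object.
#' @export
plot_rate_landscape <- function(windows, log_y = FALSE) {
  d <- windows[!is.na(windows$rate), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                       y = .data$rate)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "recombination rate") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a distance profile around anchors
#'
#' @param x A `distance_profile` from [distance_profile()].
#' @param ... Unused.
#' @return A ggplot object with the mean and its 95% band.
#' @method autoplot distance_profile
#' @export
autoplot.distance_profile <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$offset / 1e3,
                                  y = .data$mean_rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_rate - .data$ci_half,
      ymax = .data$mean_rate + .data$ci_half), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "distance from anchor (kb)",
                  y = "mean recombination rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-category rate distributions against the genome-wide rate
#'
#' @param feature_rates Output of [mean_rate_by_feature()].
#' @param genome_rate Optional genome-wide reference rate (dashed line).
#' @return A ggplot object.
#' @export
plot_category_rates <- function(feature_rates, genome_rate = NULL) {
  d <- feature_rates[!is.na(feature_rates$mean_rate), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$category,
                                       y = .data$mean_rate)) +
    ggplot2::geom_violin(scale = "width", fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "mean rate per feature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(genome_rate)) {
    p <- p + ggplot2::geom_hline(yintercept = genome_rate, linetype = 2)
  }
  p
}

#' Heatmap of a partial Kendall correlation matrix
#'
#' @param x A `partial_kendall` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot partial_kendall
#' @export
autoplot.partial_kendall <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$partial)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$partial)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial tau") +
    ggplot2::theme_minimal()
}

#' Plot paired cross-species window rates
#'
#' @param pairs Output of [align_windows()].
#' @return A ggplot object (log-log scatter with the identity line).
#' @export
plot_conservation <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$rate_a, y = .data$rate_b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "species A rate", y = "species B rate") +
    ggplot2::theme_minimal()
}
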