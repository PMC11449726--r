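# ggplot2 conveniences for the main result types. Canonical outputs are the
# tables; these are quick looks.

#' Volcano plot of signal metrics
#'
#' log2(ROR) against -log10(Bonferroni-adjusted p), combined positives
#' highlighted.
#'
#' @param metrics Output of [signal_metrics()].
#' @param label_top Number of strongest positives to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(metrics, label_top = 5) {
  v <- volcano_table(metrics)
  top <- v |>
    dplyr::filter(.data$combined_pos) |>
    dplyr::slice_max(.data$neg_log10_p_adj, n = label_top, with_ties = FALSE)
  ggplot2::ggplot(v, ggplot2::aes(.data$log2_ror, .data$neg_log10_p_adj)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$combined_pos),
                        alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$pt),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "combined positive") +
    ggplot2::labs(x = "log2(ROR)", y = "-log10(adjusted p)") +
    ggplot2::theme_minimal()
}

#' Bar chart of time-to-onset bins
#'
#' @param summary A `pv_tto_summary` from [summarize_tto()].
#' @return A ggplot object.
#' @export
plot_tto_bins <- function(summary) {
  bins <- tto_bins(summary)
  bins$bin <- factor(bins$bin, levels = bins$bin)
  ggplot2::ggplot(bins, ggplot2::aes(.data$bin, .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$pct)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "time to onset (days)", y = "reports") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_weibull Histogram of onset delays with the fitted
#'   Weibull density.
#' @param object A `pv_weibull_fit`.
#' @method autoplot pv_weibull_fit
#' @export
autoplot.pv_weibull_fit <- function(object, ...) {
  df <- tibble::tibble(days = object$data)
  grid <- tibble::tibble(days = seq(min(df$days), max(df$days),
                                    length.out = 200))
  grid$density <- dweibull(grid$days, object$shape, object$scale)
  ggplot2::ggplot(df, ggplot2::aes(.data$days)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "white") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(.data$days, .data$density),
                       colour = "firebrick") +
    ggplot2::labs(x = "time to onset (days)", y = "density",
                  subtitle = sprintf(
                    "Weibull shape %.2f [%.2f, %.2f], scale %.1f; %s",
                    object$shape, object$shape_ci[1], object$shape_ci[2],
                    object$scale, object$failure_type)) +
    ggplot2::theme_minimal()
}
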