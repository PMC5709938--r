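#' Plot rRMSE against IIV level
#'
#' Line-and-point profiles of the conventional rRMSE versus the IIV level,
#' one panel per parameter, one series per estimation method — the standard
#' display for comparing estimator precision across variability levels.
#'
#' @param metrics A `pk_metrics` tibble from [summarize_sse()].
#' @return A ggplot object.
#' @export
plot_rrmse <- function(metrics) {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$iiv_level, y = .data$rrmse,
                               colour = .data$method, shape = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "IIV level (CV%)", y = "rRMSE",
                  colour = "Method", shape = "Method") +
    ggplot2::theme_bw()
}

#' Box plots of relative estimation error
#'
#' REE distributions per estimation method, stratified by parameter (rows)
#' and IIV level (columns). An unbiased, precise estimator shows boxes
#' centred on the zero line with narrow spread. The y axis is clipped to
#' `ylim` for readability; outliers beyond it exist but are not drawn.
#'
#' @param table An `sse_table` from [run_sse()] (converted internally with
#'   [ree_table()]), or a tibble already holding a `ree` column.
#' @param ylim Two-element y-axis clip in percent.
#' @return A ggplot object.
#' @export
plot_ree <- function(table, ylim = c(-100, 100)) {
  df <- if ("ree" %in% names(table)) table else ree_table(table)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$ree,
                                   fill = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(parameter ~ iiv_level,
                        labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = ylim) +
    ggplot2::labs(x = NULL, y = "REE (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a [summarize_sse()] result draws the rRMSE profiles;
#' on a [run_sse()] table it draws the REE box plots.
#'
#' @param object A `pk_metrics` or `sse_table` object.
#' @param ... Passed on to [plot_ree()] for `sse_table`.
#' @return A ggplot object.
#' @export
autoplot.pk_metrics <- function(object, ...) plot_rrmse(object)

#' @rdname autoplot.pk_metrics
#' @export
autoplot.sse_table <- function(object, ...) plot_ree(object, ...)

#' Plot a concentration-time profile
#'
#' Convenience display of the closed-form population prediction, optionally
#' overlaid with a simulated dataset's observations.
#'
#' @param params A [pop_params()].
#' @param dose Dose (mg).
#' @param tmax Right edge of the time axis (h).
#' @param data Optional NONMEM-style dataset whose observations to overlay.
#' @return A ggplot object.
#' @export
plot_profile <- function(params, dose = 320, tmax = 24, data = NULL) {
  tt <- seq(0, tmax, length.out = 201)
  df <- tibble::tibble(TIME = tt,
                       conc = predict_concentration(params, dose, tt))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$TIME, y = .data$conc)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mg/L)") +
    ggplot2::theme_bw()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = obs_rows(data),
                                 ggplot2::aes(y = .data$DV),
                                 alpha = 0.5)
  }
  p
}
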