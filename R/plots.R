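# ggplot2 figures for the three standard outputs: tornado diagram,
# cost-effectiveness acceptability curves, and the incremental
# cost-effectiveness plane scatter with its confidence ellipse.

#' Tornado diagram
#'
#' Horizontal bars spanning the ICER reached at each parameter's lower and
#' upper plausible bound, widest swing on top, with a reference line at the
#' base-case ICER.
#'
#' @param tornado an `af_tornado` from [one_way_sensitivity()].
#' @param top show at most this many parameters (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = Inf) {
  tor <- tornado[!tornado$degenerate & is.finite(tornado$swing), , drop = FALSE]
  tor <- utils::head(tor[order(-tor$swing), , drop = FALSE], top)
  if (!nrow(tor)) stop("no finite, non-degenerate tornado entries to plot",
                       call. = FALSE)
  tor$parameter <- factor(tor$parameter, levels = rev(tor$parameter))
  ggplot2::ggplot(tor, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = tor$base_icer[1], linetype = 2) +
    ggplot2::labs(x = sprintf("ICER, %s vs %s ($/QALY)",
                              attr(tornado, "reference"),
                              attr(tornado, "comparator")),
                  y = NULL, title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param curves an `af_ceac` from [ceac()].
#' @return A ggplot object, one curve per strategy.
#' @export
plot_ceac <- function(curves) {
  strategies <- setdiff(names(curves), "wtp")
  long <- do.call(rbind, lapply(strategies, function(s)
    data.frame(wtp = curves$wtp, strategy = s, probability = curves[[s]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                     colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness plane
#'
#' Per-draw incremental points with the normal-theory coverage ellipse and,
#' optionally, a willingness-to-pay ray through the origin.
#'
#' @param ice an `af_ice` from [ice_scatter()].
#' @param wtp optional WTP threshold to draw as a line through the origin.
#' @return A ggplot object.
#' @export
plot_ice <- function(ice, wtp = NULL) {
  p <- ggplot2::ggplot(ice$points, ggplot2::aes(x = .data$dqaly,
                                                y = .data$dcost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "grey30") +
    ggplot2::geom_path(data = ice$ellipse, colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (%s vs %s)", ice$reference, ice$comparator),
      y = "Incremental cost ($)",
      title = sprintf("Incremental cost-effectiveness plane (%.0f%% ellipse)",
                      100 * ice$coverage)) +
    ggplot2::theme_minimal()
  if (!is.null(wtp))
    p <- p + ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = 2)
  p
}
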