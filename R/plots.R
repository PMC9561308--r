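#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars spanning each parameter's ICER range, widest on
#' top, with the base-case ICER marked.
#'
#' @param dsa A `dsa_result` from [one_way_dsa()].
#' @param top Number of parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, top = nrow(dsa)) {
  d <- utils::head(as.data.frame(dsa), top)
  d$path <- factor(d$path, levels = rev(d$path))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       y = .data$path, yend = .data$path),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = d$icer_base[1], linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(psa$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = psa$wtp, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "P(intervention cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter
#'
#' Incremental cost vs incremental QALYs per PSA iteration, with the
#' willingness-to-pay line through the origin and a 95% normal
#' ellipse of the cloud.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  it <- psa$iterations
  ggplot2::ggplot(it, ggplot2::aes(x = .data$delta_qaly,
                                   y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "steelblue") +
    ggplot2::stat_ellipse(level = 0.95, colour = "black") +
    ggplot2::geom_abline(intercept = 0, slope = psa$wtp, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
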