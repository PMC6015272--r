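#' Cost-effectiveness plane scatter
#'
#' Bootstrap replicates of (incremental QALY, incremental cost) with the
#' axes and willingness-to-pay threshold lines.
#'
#' @param object A `boot_cloud`.
#' @param wtp Threshold slopes (GBP/QALY) drawn through the origin.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boot_cloud <- function(object, wtp = c(20000, 30000), ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$delta_qaly,
                                    y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue4") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (£)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  for (l in wtp) {
    p <- p + ggplot2::geom_abline(slope = l, intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  p
}

#' @rdname autoplot.boot_cloud
#' @param cloud A `boot_cloud`.
#' @export
plot_ce_plane <- function(cloud, wtp = c(20000, 30000)) {
  autoplot.boot_cloud(cloud, wtp)
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `ceac_curve` from [ceac()].
#' @param wtp_marks Thresholds highlighted with vertical reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ceac_curve <- function(object, wtp_marks = c(20000, 30000), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = wtp_marks, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (£ per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ceac_curve
#' @param curve A `ceac_curve`.
#' @export
plot_ceac <- function(curve, wtp_marks = c(20000, 30000)) {
  autoplot.ceac_curve(curve, wtp_marks)
}

#' ICER versus number of users
#'
#' One-way sensitivity plot: the cost-effectiveness ratio as fixed annual
#' costs are spread over more users, with the conventional threshold band.
#'
#' @param object A `scaling_result` from [icer_vs_users()].
#' @param thresholds Horizontal reference lines (GBP/QALY).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scaling_result <- function(object, thresholds = c(20000, 30000), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_users, y = .data$icer)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Number of users (log scale)",
                  y = "ICER (£ per QALY)",
                  title = "One-way sensitivity: ICER vs number of users") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scaling_result
#' @param scaling A `scaling_result`.
#' @export
plot_icer_scaling <- function(scaling, thresholds = c(20000, 30000)) {
  autoplot.scaling_result(scaling, thresholds)
}
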