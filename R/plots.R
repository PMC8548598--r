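#' Plot luminescence traces
#'
#' @param data Long trace tibble (`trace`, `time_h`, `value`).
#' @param colour_by Column mapped to colour (default `trace`).
#' @return A ggplot.
#' @export
plot_traces <- function(data, colour_by = "trace") {
  check_trace_tbl(data)
  ggplot2::ggplot(data, ggplot2::aes(.data$time_h, .data$value,
                                     group = .data$trace,
                                     colour = .data[[colour_by]])) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (h)", y = "luminescence (a.u.)")
}

#' Plot a Kuramoto synchrony curve
#'
#' K against the end of the expanding averaging interval, with the
#' conventional 0.7 guide line.
#'
#' @param curve A [kuramoto_curve()] tibble.
#' @return A ggplot.
#' @export
plot_kuramoto <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$t_end_h / 24, .data$K)) +
    ggplot2::geom_hline(yintercept = 0.7, colour = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "interval end (d)", y = "Kuramoto order parameter K")
}

#' Polar acrophase diagram
#'
#' Arrows at each acrophase (angle, 24-h clock) with length equal to
#' amplitude.
#'
#' @param acrophase_h Acrophases in hours.
#' @param amplitude Amplitudes (a.u.), recycled if length 1.
#' @param group Optional grouping factor mapped to colour.
#' @return A ggplot in polar coordinates.
#' @export
plot_acrophase_polar <- function(acrophase_h, amplitude = 1, group = NULL) {
  df <- tibble(acrophase_h = wrap_24(acrophase_h),
               amplitude = rep_len(amplitude, length(acrophase_h)),
               group = if (is.null(group)) "all" else as.character(group))
  ggplot2::ggplot(df, ggplot2::aes(.data$acrophase_h, .data$amplitude,
                                   colour = .data$group)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$acrophase_h, yend = 0),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                                                 ends = "first")) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 21, by = 3)) +
    ggplot2::labs(x = "acrophase (h)", y = "amplitude (a.u.)", colour = NULL)
}

#' Polar histogram of rhythmic-gene peak times
#'
#' @param pdn A [phase_day_night()] result.
#' @return A ggplot in polar coordinates.
#' @export
plot_phase_histogram <- function(pdn) {
  bins <- pdn$bins[[1]]
  ggplot2::ggplot(bins, ggplot2::aes(.data$bin_mid_h, .data$count)) +
    ggplot2::geom_col(width = diff(bins$bin_start_h[1:2]), fill = "#1b9e77") +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 21, by = 3)) +
    ggplot2::labs(x = "peak time (h)", y = "genes")
}

#' Phase-ordered heatmap of rhythmic genes
#'
#' @param hm A [heatmap_matrix()] long tibble.
#' @return A ggplot tile heatmap, rows ordered by phase.
#' @export
plot_phase_heatmap <- function(hm) {
  ggplot2::ggplot(hm, ggplot2::aes(.data$timepoint_h, .data$gene,
                                   fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = "time (h)", y = NULL, fill = "scaled cpm") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
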