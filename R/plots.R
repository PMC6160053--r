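#' Rose diagram of azimuthal orientation
#'
#' Plots sector counts from [rose_bins()] (or raw angles) on a polar
#' coordinate system. Rose diagrams have no preferred orientation relative
#' to the specimen; they show whether the in-plane trabecular orientation
#' is uniform or directional.
#'
#' @param x A [rose_bins()] tibble or a numeric vector of angles in
#'   degrees.
#' @param bins Number of sectors when `x` is a vector of angles.
#' @return A ggplot object.
#' @export
plot_rose <- function(x, bins = 36) {
  if (is.numeric(x)) x <- rose_bins(x, bins)
  ggplot2::ggplot(x, ggplot2::aes(
    x = (.data$start_deg + .data$end_deg) / 2, y = .data$count
  )) +
    ggplot2::geom_col(width = 360 / nrow(x), fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = expression(phi ~ "(deg)"), y = "count") +
    ggplot2::theme_minimal()
}

#' Histogram of trabecular inclination theta
#'
#' @param segments A [segment_table()] tibble.
#' @param binwidth Bin width in degrees.
#' @return A ggplot object.
#' @export
plot_theta_histogram <- function(segments, binwidth = 5) {
  df <- segments[!is.na(segments$theta), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::scale_x_continuous(limits = c(0, 90)) +
    ggplot2::labs(x = expression(theta ~ "(deg)"), y = "count") +
    ggplot2::theme_minimal()
}

#' Histogram of inter-trabecular angles
#'
#' @param nodes A [node_table()] tibble.
#' @param binwidth Bin width in degrees.
#' @param valence Optional valence class filter (e.g. 3 for 3N nodes).
#' @return A ggplot object.
#' @export
plot_ita_histogram <- function(nodes, binwidth = 5, valence = NULL) {
  if (!is.null(valence)) {
    nodes <- nodes[nodes$valence %in% valence, , drop = FALSE]
  }
  df <- tibble(ita = unlist(nodes$ita))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ita)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::scale_x_continuous(limits = c(0, 180)) +
    ggplot2::labs(x = "inter-trabecular angle (deg)", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Distribution of subsample p-values of a comparison
#'
#' @param object A `trab_comparison` from [subsampled_wilcoxon()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trab_comparison <- function(object, ...) {
  df <- tibble(p = object$p_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$mean_p, linetype = 2) +
    ggplot2::labs(x = "subsample p-value", y = "count",
                  subtitle = sprintf("mean p = %.3g", object$mean_p)) +
    ggplot2::theme_minimal()
}
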