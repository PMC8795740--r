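# ggplot2 visualisations for the main result types.

#' Plot a trajectory in its arena
#'
#' @param traj A trajectory tibble.
#' @param arena Optional [arena()] drawn as the bounding walls.
#' @param colour Path colour.
#'
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, arena = NULL, colour = "grey30") {
  check_trajectory(traj)
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = colour, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
  if (!is.null(arena)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = 0, xmax = arena$width, ymin = 0, ymax = arena$height,
      fill = NA, colour = "black"
    )
  }
  p
}

#' Plot a rate map
#'
#' @param map A tibble from [rate_map()] (columns `x`, `y`, `rate`).
#'
#' @return A ggplot object.
#' @export
plot_rate_map <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gp_calibration <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase, y = .data$displacement)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(
      x = "unwrapped stripe phase (cells)",
      y = "displacement along preferred direction (m)",
      title = sprintf("r = %.5f, max |residual| = %.3f m", object$r,
                      object$max_residual)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gp_formation_study <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$formation_ms)) +
    ggplot2::geom_histogram(binwidth = 50, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "formation time (ms)", y = "runs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gp_error_stats <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$error)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$envelope), colour = "red",
                       linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "position error (m)") +
    ggplot2::theme_minimal()
}

#' Plot the error series of a boundary-correction comparison
#'
#' @param comparison The list returned by [run_boundary_comparison()].
#'
#' @return A ggplot object, one line per method averaged over seeds.
#' @export
plot_boundary_comparison <- function(comparison) {
  d <- dplyr::summarise(
    dplyr::group_by(comparison$series, .data$t, .data$method),
    error = mean(.data$error), .groups = "drop"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$error,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean position error (m)") +
    ggplot2::theme_minimal()
}
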