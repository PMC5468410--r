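#' Plot the trajectory of the training metric across session pairs
#'
#' Lines for the three normalized measures (mean performance, performance
#' stability, cognitive stability) and the normalized triangle area, one
#' point per pair of consecutive sessions.
#'
#' @param object A `training_course` from [run_course()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_course <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$pairs[, c("pair", "mean_performance", "performance_stability",
                     "cognitive_stability", "area_normalized")],
    -"pair", names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure,
                         levels = c("mean_performance", "performance_stability",
                                    "cognitive_stability", "area_normalized"),
                         labels = c("Mean performance", "Performance stability",
                                    "Cognitive stability", "Training level (area)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$pair)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Session pair", y = "Normalized value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Draw the training-level triangle of one session pair
#'
#' The three normalized measures are drawn as distances from the centroid,
#' 120 degrees apart, against the unit reference triangle whose area defines
#' the maximum training level.
#'
#' @param a,b,c Mean performance, performance stability and cognitive
#'   stability, each in `[0, 1]`.
#' @return A ggplot object (the normalized area is shown in the subtitle).
#' @export
plot_training_triangle <- function(a, b, c) {
  tri <- triangle_area(a, b, c)
  ang <- c(90, 210, 330) * pi / 180
  vertex <- function(r) tibble::tibble(x = r * cos(ang), y = r * sin(ang))
  unit <- vertex(c(1, 1, 1))
  obs <- vertex(c(a, b, c))
  lab <- tibble::tibble(
    x = 1.25 * cos(ang), y = 1.25 * sin(ang),
    text = c("Mean\nperformance", "Performance\nstability",
             "Cognitive\nstability"))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = unit, ggplot2::aes(.data$x, .data$y),
                          fill = NA, colour = "grey60", linetype = 2) +
    ggplot2::geom_polygon(data = obs, ggplot2::aes(.data$x, .data$y),
                          fill = "steelblue", alpha = 0.5, colour = "steelblue4") +
    ggplot2::geom_text(data = lab, ggplot2::aes(.data$x, .data$y, label = .data$text),
                       size = 3) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.3, 1.5)) +
    ggplot2::labs(subtitle = sprintf("Normalized area = %.3f",
                                     tri$area_normalized)) +
    ggplot2::theme_void()
}
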