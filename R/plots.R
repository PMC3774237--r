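#' Plot the feasible intake-rate "kite" of a diet solution
#'
#' Shows the feasible (X, Y) region's vertices, the digestive constraint
#' line, and the optimal policy for a two-prey solution.
#'
#' @param object a `diet_solution`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.diet_solution <- function(object, ...) {
  verts <- feasible_vertices(object$prey, object$forager)
  hull <- verts[grDevices::chull(verts$X, verts$Y), ]
  p <- ggplot2::ggplot(verts, ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_polygon(data = hull, fill = "grey85", colour = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::annotate("point", x = object$rates$X, y = object$rates$Y,
                      shape = 8, size = 3, colour = "red") +
    ggplot2::labs(x = "ballast intake rate X (mg shell DM / s)",
                  y = "energy intake rate Y (mg AFDM / s)",
                  title = paste0("optimal diet (", object$model_used, ")")) +
    ggplot2::theme_minimal()
  if (!is.null(object$forager)) {
    p <- p + ggplot2::geom_vline(xintercept = object$forager$c_mg_s,
                                 linetype = "dashed")
  }
  p
}

#' Plot a functional-response curve table
#'
#' @param curve output of [functional_response_curve()].
#' @param y_req optional subsistence intake rate drawn as a horizontal line.
#' @return A ggplot of intake rate vs. bulky-prey biomass, with and without
#'   the toxic prey, one panel line pair per toxic-prey biomass level.
#' @export
plot_functional_response <- function(curve, y_req = NULL) {
  long <- tidyr::pivot_longer(curve, c("Y_with", "Y_without"),
                              names_to = "diet", values_to = "Y")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$b_bulk, y = .data$Y,
                                          linetype = .data$diet,
                                          colour = factor(.data$b_tox))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bulky prey biomass (g AFDM / m2)",
                  y = "optimal intake rate Y (mg AFDM / s)",
                  colour = "toxic prey\nbiomass", linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(y_req)) {
    p <- p + ggplot2::geom_hline(yintercept = y_req, linetype = "dotted")
  }
  p
}

#' Plot a diet-composition curve table
#'
#' @param curve output of [diet_fraction_curve()].
#' @return A ggplot of the toxic prey's diet fraction vs. bulky-prey
#'   biomass.
#' @export
plot_diet_fraction <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$b_bulk, y = .data$frac_tox,
                                      colour = factor(.data$b_tox))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bulky prey biomass (g AFDM / m2)",
                  y = "toxic prey fraction of diet (flesh basis)",
                  colour = "toxic prey\nbiomass") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot population trajectories
#'
#' @param trajectories one or more row-bound outputs of
#'   [scenario_project()] or [project_population()]; a `scenario` column, if
#'   present, colours the lines.
#' @return A ggplot of total counts over years.
#' @export
plot_trajectory <- function(trajectories) {
  aes <- if ("scenario" %in% names(trajectories)) {
    ggplot2::aes(x = .data$year, y = .data$n_total, colour = .data$scenario)
  } else {
    ggplot2::aes(x = .data$year, y = .data$n_total)
  }
  ggplot2::ggplot(trajectories, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "year", y = "population size") +
    ggplot2::theme_minimal()
}
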