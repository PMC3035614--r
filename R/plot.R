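#' Plot the zero-net-growth isoclines
#'
#' Draws both isoclines in the plane of juvenile vs adult abundance and marks
#' the interior coexistence equilibria (solid: stable, open: unstable).
#'
#' @inheritParams zngi_curves
#' @return A ggplot object.
#' @export
#' @examples
#' plot_zngi(default_params("additional"))
plot_zngi <- function(params, C_max = NULL, n = 201) {
  curves <- zngi_curves(params, C_max = C_max, n = n)
  eq <- coexistence_equilibria(params)
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$C_J, y = .data$C_A)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$curve)) +
    ggplot2::scale_linetype_manual(values = c(ZNGI_A = "solid",
                                              ZNGI_J = "dashed")) +
    ggplot2::labs(x = expression(C[J]^"*"), y = expression(C[A]^"*"),
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (nrow(eq) > 0) {
    eq$stable <- eq$stability == "stable"
    p <- p + ggplot2::geom_point(
      data = eq, ggplot2::aes(shape = .data$stable), size = 2.5
    ) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                  labels = c(`TRUE` = "stable",
                                             `FALSE` = "unstable"),
                                  name = NULL)
  }
  p
}

#' Plot an ASS scan as a region map
#'
#' @param object An `ass_scan` result from [scan_ass_region()].
#' @param ... Unused.
#' @return A ggplot object (raster map; cells with alternative stable states
#'   filled green).
#' @method autoplot ass_scan
#' @export
autoplot.ass_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$ass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2E8B57",
                                          `FALSE` = "grey90"),
                               na.value = "white", name = "ASS") +
    ggplot2::labs(x = attr(object, "x_param"), y = attr(object, "y_param")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' @param object A `niche_trajectory` from [integrate_model()].
#' @param ... Unused.
#' @return A ggplot object (one line per state component).
#' @method autoplot niche_trajectory
#' @export
autoplot.niche_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "component", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$abundance,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
}
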