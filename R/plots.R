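#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Ki-67 heat map
#' @param object A `ki67_heatmap`.
#' @param ... Unused.
#' @return A ggplot raster of the smoothed DAB OD with masked cells blank.
#' @export
autoplot.ki67_heatmap <- function(object, ...) {
  df <- expand.grid(x_um = object$x_um, y_um = object$y_um)
  df$value <- as.numeric(object$values)
  df$value[as.logical(object$mask)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "DAB OD\n(smoothed)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Nucleus DAB OD mean, smoothed %g µm",
                                  object$smoothing_radius_um))
}

#' Bland-Altman plot
#' @param object A `ki67_ba` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot with bias and limits of agreement.
#' @export
autoplot.ki67_ba <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "Mean of methods (%)",
                  y = "Difference (comparator - reference, %)")
}

#' Plot cumulative incidence curves
#' @param object A `ki67_cif` from [cumulative_incidence()].
#' @param event Event to plot (default `"bc_death"`).
#' @param ... Unused.
#' @return A ggplot of per-group step functions.
#' @export
autoplot.ki67_cif <- function(object, event = "bc_death", ...) {
  df <- object[object$event == event, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years since diagnosis",
                  y = "Cumulative incidence",
                  colour = NULL,
                  title = paste("Cumulative incidence of", event))
}

#' Plot nuclei coloured by class and Ki-67 positivity
#'
#' Works for ground-truth tables and classified detections alike.
#'
#' @param detections Tibble with `x_um`, `y_um`, a class column and
#'   optionally `ki67_positive`.
#' @return A ggplot point map of the scene.
#' @export
plot_nuclei <- function(detections) {
  df <- tibble::tibble(
    x_um = detections$x_um, y_um = detections$y_um,
    class = detection_class(detections),
    positive = if ("ki67_positive" %in% names(detections))
      detections$ki67_positive else FALSE
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   colour = .data$class,
                                   shape = .data$positive)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "Ki-67+") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "class")
}
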