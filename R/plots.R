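#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a CRB map
#'
#' Raster map of the bound (or of the effective uncertainty when present)
#' over the field of view.
#'
#' @param object A [crb_map()] tibble.
#' @param what Column to map to fill; default `sigma_eff` if present, else
#'   `sigma_crb`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crb_map <- function(object, what = NULL, ...) {
  if (is.null(what)) what <- if ("sigma_eff" %in% names(object)) "sigma_eff" else "sigma_crb"
  ggplot2::ggplot(object, ggplot2::aes(.data$x_nm, .data$y_nm,
                                       fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0(what, " (nm)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' Plot an intensity trace with threshold and events
#'
#' @param trace Trace tibble from [trace_from_tensor()].
#' @param threshold Optional threshold to draw.
#' @param events Optional event table from [segment_events()].
#' @return A ggplot.
#' @export
plot_trace <- function(trace, threshold = NULL, events = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$orbit, .data$photons)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "orbit", y = "photons / orbit")
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(threshold),
                                 linetype = 2, color = "red")
  }
  p
}

#' Plot event localizations
#'
#' @param object An `ismflux_events` table.
#' @param ... Unused.
#' @return A ggplot of accepted (and rejected) localizations.
#' @export
autoplot.ismflux_events <- function(object, ...) {
  df <- object[!object$degenerate, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm,
                                   color = .data$accepted)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", color = "accepted")
}

#' Plot a rendered localization image
#'
#' @param object An `ismflux_render` from [reconstruct()].
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.ismflux_render <- function(object, ...) {
  df <- expand.grid(x_nm = object$x, y_nm = object$y)
  df$value <- as.vector(object$image)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' Plot a self-calibration spread curve
#'
#' @param object A `self_calibration`.
#' @param ... Unused.
#' @return A ggplot of quadrant spread versus candidate L.
#' @export
autoplot.self_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$L, .data$spread_nm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$L_best, linetype = 2) +
    ggplot2::labs(x = "candidate L (nm)", y = "quadrant spread (nm)")
}
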