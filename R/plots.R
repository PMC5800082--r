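#' Plot a hatch-curve fit
#'
#' Mean hatch success against exposure duration with the fitted curve
#' overlaid.
#'
#' @param object A `hatch_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hatch_fit <- function(object, ...) {
  grid <- tibble::tibble(
    exposure_days = seq(0, max(object$data$exposure_days), length.out = 200)
  )
  grid$hatch_pct <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$exposure_days, y = .data$mean_hatch_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$hatch_pct)) +
    ggplot2::labs(x = "Exposure duration (days)", y = "Hatch success (%)",
                  title = paste0("Hatch curve (", object$family, " fit)")) +
    ggplot2::ylim(0, 100)
}

#' Plot a Briere-1 thermal performance fit
#'
#' Observed performance points with the fitted curve and the cardinal
#' temperatures marked.
#'
#' @param object A `briere_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.briere_fit <- function(object, ...) {
  grid <- tibble::tibble(
    temperature_C = seq(object$t_min - 2, object$t_max + 2, by = 0.1)
  )
  grid$performance <- predict(object, grid)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$temperature_C, y = .data$performance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = c(object$t_min, object$t_opt, object$t_max),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression("Cumulative female survival" ~ (day^-1)))
}

#' Plot a single-band grid (voltinism or frost map)
#'
#' @param raster A tibble with `x`, `y` and one value column.
#' @param value_col Column to plot; default the first non-coordinate
#'   column.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster, value_col = NULL) {
  check_columns(raster, c("x", "y"))
  if (is.null(value_col)) value_col <- setdiff(names(raster), c("x", "y"))[1]
  ggplot2::ggplot(raster, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data[[value_col]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = value_col)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
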