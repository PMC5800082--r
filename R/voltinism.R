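#' Generation-time model
#'
#' The generation time (days from egg hatch of one generation to first
#' oviposition of the next) as a function of temperature,
#' \deqn{G(T) = A e^{-kT} + c,}
#' obtained from the exponential age-at-emergence fit with a fixed
#' pre-oviposition shift already folded into the asymptote `c`. With the
#' default coefficients, G(25) is about 26.5 days.
#'
#' @param A Amplitude (days); default 290.75.
#' @param k Decay rate (per degree C); default 0.17.
#' @param c Asymptotic generation time at high temperature (days);
#'   default 22.32, which includes the pre-oviposition shift.
#' @param shift_days Pre-oviposition period folded into `c` (days);
#'   default 14. Kept for provenance; not applied again.
#' @return A `gen_time_model` object.
#' @examples
#' g <- gen_time_model()
#' generation_time(25, g)
#' @export
gen_time_model <- function(A = 290.75, k = 0.17, c = 22.32, shift_days = 14) {
  stopifnot(A >= 0, k > 0, c > 0)
  structure(list(A = A, k = k, c = c, shift_days = shift_days),
            class = "gen_time_model")
}

#' Build a generation-time model from an age-at-emergence fit
#'
#' Adds the pre-oviposition shift (days between adult emergence and first
#' oviposition) to the asymptote of an exponential emergence-age fit.
#'
#' @param fit An `age_fit` for the emergence trait (see [fit_age_curve()]).
#' @param shift_days Pre-oviposition period in days (default 14).
#' @return A `gen_time_model`.
#' @export
gen_time_from_emergence <- function(fit, shift_days = 14) {
  stopifnot(inherits(fit, "age_fit"))
  if (fit$trait != "emergence") {
    warning("generation time is conventionally built from the emergence trait, got ",
            fit$trait)
  }
  cf <- fit$coefficients
  gen_time_model(A = cf[["A"]], k = cf[["k"]], c = cf[["c"]] + shift_days,
                 shift_days = shift_days)
}

#' @export
print.gen_time_model <- function(x, ...) {
  cat(sprintf("Generation-time model: G(T) = %.2f * exp(-%.2f T) + %.2f days\n",
              x$A, x$k, x$c))
  invisible(x)
}

#' Generation time at a given temperature
#'
#' @param temp_C Numeric vector of temperatures (degrees C).
#' @param model A `gen_time_model` (default coefficients if omitted).
#' @return Generation time(s) in days; strictly decreasing in temperature,
#'   approaching `model$c` as temperature grows.
#' @export
generation_time <- function(temp_C, model = gen_time_model()) {
  stopifnot(inherits(model, "gen_time_model"))
  model$A * exp(-model$k * temp_C) + model$c
}

# days per month, 365-day non-leap calendar
days_in_month_365 <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Potential generations per year from monthly mean temperatures
#'
#' Accumulates generations month by month as days-in-month divided by the
#' generation time at that month's mean temperature:
#' \deqn{N = \sum_{months} d_{month} / G(T_{month}).}
#' By default no low-temperature cutoff is applied — G(T) is evaluated even
#' below the developmental minimum, where contributions become negligible
#' but non-zero; set `t_cutoff` for a sensitivity analysis where months
#' below the cutoff contribute nothing.
#'
#' @param monthly_temps Numeric vector of 12 monthly mean temperatures
#'   (degrees C), January first.
#' @param model A `gen_time_model`.
#' @param calendar Month lengths in days; default the real 365-day
#'   non-leap calendar.
#' @param t_cutoff Optional lower temperature cutoff (degrees C).
#' @return Potential generations per year (dimensionless scalar); `NA` if
#'   any month is missing.
#' @examples
#' annual_generations(rep(25, 12))  # ~13.8
#' @export
annual_generations <- function(monthly_temps, model = gen_time_model(),
                               calendar = days_in_month_365, t_cutoff = NULL) {
  if (length(monthly_temps) != 12 || length(calendar) != 12) {
    stop("annual_generations expects 12 monthly temperatures and 12 month lengths")
  }
  if (anyNA(monthly_temps) || any(!is.finite(monthly_temps))) return(NA_real_)
  contrib <- calendar / generation_time(monthly_temps, model)
  if (!is.null(t_cutoff)) contrib[monthly_temps < t_cutoff] <- 0
  sum(contrib)
}

#' Map potential generations per year over a monthly temperature grid
#'
#' Applies [annual_generations()] to every grid cell of a long-format
#' monthly temperature table. Cells with any missing month propagate as
#' no-data.
#'
#' @param raster Monthly temperature grid: tibble with columns `x`, `y`,
#'   `month` (1-12) and `temp_C` (see [simulate_monthly_raster()] /
#'   [read_monthly_raster()]).
#' @inheritParams annual_generations
#' @return A tibble with `x`, `y`, `generations`, carrying attribute
#'   `"summary"` (a tibble with mean, min, max over the unmasked cells).
#' @export
voltinism_map <- function(raster, model = gen_time_model(),
                          calendar = days_in_month_365, t_cutoff = NULL) {
  check_columns(raster, c("x", "y", "month", "temp_C"))
  out <- raster |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(
      generations = if (dplyr::n() == 12 && !anyNA(.data$temp_C)) {
        annual_generations(.data$temp_C[order(.data$month)], model,
                           calendar, t_cutoff)
      } else NA_real_,
      .groups = "drop"
    )
  ok <- out$generations[!is.na(out$generations)]
  attr(out, "summary") <- tibble::tibble(
    n_cells = length(ok),
    mean = if (length(ok)) mean(ok) else NA_real_,
    min = if (length(ok)) min(ok) else NA_real_,
    max = if (length(ok)) max(ok) else NA_real_
  )
  out
}

#' Midpoint of monthly minimum and maximum temperature grids
#'
#' Combines the monthly average minimum and maximum temperature layers of
#' a climate scenario into a single mean-temperature grid by the per-cell,
#' per-month midpoint (tmin + tmax) / 2.
#'
#' @param tmin_raster,tmax_raster Long-format monthly grids (`x`, `y`,
#'   `month`, `temp_C`) on the same grid.
#' @return A monthly grid tibble of midpoints.
#' @export
scenario_temperatures <- function(tmin_raster, tmax_raster) {
  check_columns(tmin_raster, c("x", "y", "month", "temp_C"))
  check_columns(tmax_raster, c("x", "y", "month", "temp_C"))
  joined <- dplyr::inner_join(tmin_raster, tmax_raster,
                              by = c("x", "y", "month"),
                              suffix = c("_min", "_max"))
  if (nrow(joined) != nrow(tmin_raster) || nrow(joined) != nrow(tmax_raster)) {
    stop("tmin and tmax grids do not share the same cells/months")
  }
  joined |>
    dplyr::transmute(.data$x, .data$y, .data$month,
                     temp_C = (.data$temp_C_min + .data$temp_C_max) / 2)
}

#' Crop a gridded table to a bounding box
#'
#' @param raster Any grid tibble with `x` and `y` columns.
#' @param xmin,xmax,ymin,ymax Bounding box (inclusive).
#' @return The subset of cells inside the box.
#' @export
crop_raster <- function(raster, xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = Inf) {
  check_columns(raster, c("x", "y"))
  out <- dplyr::filter(raster, .data$x >= xmin, .data$x <= xmax,
                       .data$y >= ymin, .data$y <= ymax)
  attr(out, "summary") <- NULL  # any whole-map summary is stale after a crop
  out
}

#' Extract grid values at point locations
#'
#' Nearest-cell (not interpolated) lookup of a single-band grid at a set
#' of points. Points farther from every cell centre than one cell size are
#' flagged as outside the extent and get no value.
#'
#' @param raster A single-band grid tibble, e.g. from [voltinism_map()]
#'   (`x`, `y` and one value column).
#' @param points A tibble with `point_id`, `x`, `y`.
#' @param value_col Name of the value column; defaults to the first
#'   non-coordinate column.
#' @return A tibble: `point_id`, `x`, `y`, `<value_col>`, `inside`
#'   (logical).
#' @export
extract_points <- function(raster, points, value_col = NULL) {
  check_columns(raster, c("x", "y"))
  check_columns(points, c("point_id", "x", "y"))
  if (is.null(value_col)) {
    value_col <- setdiff(names(raster), c("x", "y"))[1]
  }
  xs <- sort(unique(raster$x)); ys <- sort(unique(raster$y))
  resx <- if (length(xs) > 1) min(diff(xs)) else 1
  resy <- if (length(ys) > 1) min(diff(ys)) else 1
  res <- purrr::map_dfr(seq_len(nrow(points)), function(i) {
    dx <- abs(raster$x - points$x[i]); dy <- abs(raster$y - points$y[i])
    j <- which.min(dx^2 + dy^2)
    inside <- dx[j] <= resx / 2 + 1e-9 && dy[j] <= resy / 2 + 1e-9
    tibble::tibble(
      point_id = points$point_id[i], x = points$x[i], y = points$y[i],
      value = if (inside) raster[[value_col]][j] else NA_real_,
      inside = inside
    )
  })
  names(res)[names(res) == "value"] <- value_col
  res
}
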