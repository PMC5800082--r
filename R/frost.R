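#' Count frost events in a daily temperature series
#'
#' A frost event is a maximal run of at least `min_run_days` consecutive
#' days with daily temperature at or below `threshold` — the
#' experimentally determined larval-lethal condition (three or more days
#' at 0 degrees C or lower). A run counts once regardless of its length;
#' runs are non-overlapping by construction. A declared gap in the dates
#' splits any run that spans it; a run spanning a year boundary is
#' attributed to the year it starts in.
#'
#' @param series A data frame with columns `date` (Date, strictly
#'   increasing) and `temp_C`, or a bare numeric vector of consecutive
#'   daily temperatures.
#' @param threshold Temperature threshold (degrees C, inclusive);
#'   default 0.
#' @param min_run_days Minimum run length in days; default 3.
#' @return A one-row `frost_summary` tibble: `n_events`, `n_days`,
#'   `n_years` (exact span / 365.25), `events_per_year`, plus attribute
#'   `"events"`: a tibble of the individual runs (`start`, `end`,
#'   `length_days`, `year`).
#' @examples
#' count_frost_events(c(-1, -1, -1, 5, -1, -1))
#' @export
count_frost_events <- function(series, threshold = 0, min_run_days = 3) {
  if (is.numeric(series)) {
    series <- tibble::tibble(
      date = as.Date("2000-01-01") + seq_along(series) - 1,
      temp_C = as.numeric(series)
    )
  }
  check_columns(series, c("date", "temp_C"))
  if (nrow(series) == 0) stop("empty temperature series")
  series <- dplyr::arrange(series, .data$date)
  if (any(duplicated(series$date))) stop("duplicated dates in series")
  d <- as.integer(diff(series$date))
  # a date gap splits the series: a candidate run may not bridge it
  segment <- cumsum(c(0L, as.integer(d > 1L)))
  cold <- series$temp_C <= threshold & !is.na(series$temp_C)
  # NA temperatures also split runs (missing day of unknown state)
  segment <- segment + cumsum(is.na(series$temp_C))
  events <- list()
  for (seg in split(seq_len(nrow(series)), segment)) {
    r <- rle(cold[seg])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_run_days
    for (i in which(keep)) {
      idx <- seg[starts[i]:ends[i]]
      events[[length(events) + 1]] <- tibble::tibble(
        start = series$date[idx[1]],
        end = series$date[idx[length(idx)]],
        length_days = length(idx),
        year = as.integer(format(series$date[idx[1]], "%Y"))
      )
    }
  }
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(start = as.Date(character()), end = as.Date(character()),
                   length_days = integer(), year = integer())
  n_days <- as.numeric(max(series$date) - min(series$date)) + 1
  n_years <- n_days / 365.25
  out <- tibble::tibble(
    n_events = nrow(ev),
    n_days = n_days,
    n_years = n_years,
    events_per_year = nrow(ev) / n_years
  )
  attr(out, "events") <- ev
  class(out) <- c("frost_summary", class(out))
  out
}

#' Map frost events per year over a daily temperature grid
#'
#' Applies [count_frost_events()] to each cell of a long-format daily
#' temperature grid. Cells whose series is entirely missing propagate as
#' no-data.
#'
#' @param grid A tibble with columns `x`, `y`, `date`, `temp_C`.
#' @inheritParams count_frost_events
#' @return A tibble: `x`, `y`, `events_per_year` (`NA` for all-missing
#'   cells).
#' @export
frost_map <- function(grid, threshold = 0, min_run_days = 3) {
  check_columns(grid, c("x", "y", "date", "temp_C"))
  grid |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(
      events_per_year = if (all(is.na(.data$temp_C))) NA_real_ else {
        count_frost_events(dplyr::pick("date", "temp_C"),
                           threshold = threshold,
                           min_run_days = min_run_days)$events_per_year
      },
      .groups = "drop"
    )
}
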