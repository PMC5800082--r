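#' Read and write pipeline tables
#'
#' Thin readr wrappers that check the required columns for each input
#' kind. All tables are UTF-8 CSV with a header row; gridded data is
#' stored long (one row per cell and month/day).
#'
#' @param path File path.
#' @name mosqtherm_io
NULL

#' @describeIn mosqtherm_io Egg cold-exposure records
#'   (`temperature_C, exposure_days, cup_id, n_eggs, n_hatched`).
#' @export
read_egg_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("temperature_C", "exposure_days", "cup_id", "n_eggs", "n_hatched"))
  df
}

#' @describeIn mosqtherm_io Individual life-history records
#'   (`temperature_C, cup_id, sex, survived, age_*_days, r1_mm`).
#' @export
read_life_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("temperature_C", "cup_id", "sex", "survived",
                      "age_pupation_days", "age_emergence_days",
                      "age_death_days", "r1_mm"))
  df
}

#' @describeIn mosqtherm_io Monthly temperature grid, long format
#'   (`x, y, month, temp_C`). Integer-packed storage (`temp_C` = degrees C
#'   x 10) is unpacked when `scale_factor` is given.
#' @param scale_factor Divide stored values by this factor (e.g. 10 for
#'   tenth-degree integer packing); default 1.
#' @export
read_monthly_raster <- function(path, scale_factor = 1) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("x", "y", "month", "temp_C"))
  df$temp_C <- df$temp_C / scale_factor
  df
}

#' @describeIn mosqtherm_io Daily temperature series (`date, temp_C`).
#' @export
read_daily_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("date", "temp_C"))
  df$date <- as.Date(df$date)
  df
}

#' @describeIn mosqtherm_io Write any pipeline table as CSV.
#' @param x A data frame.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
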