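#' Write a complete set of synthetic input fixtures
#'
#' Generates all four input kinds (egg exposure table, life-history
#' table, monthly temperature grid, daily temperature series) from the
#' default ground truth and writes them as CSV, with the truth parameters
#' serialised as JSON alongside.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed controlling every simulator.
#' @param design An [experiment_design()].
#' @param truth A [ground_truth()].
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixtures <- function(dir, seed = 1L, design = experiment_design(),
                          truth = ground_truth()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    eggs = file.path(dir, "egg_records.csv"),
    life = file.path(dir, "life_records.csv"),
    monthly = file.path(dir, "monthly_temperature.csv"),
    daily = file.path(dir, "daily_temperature.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_table_csv(simulate_egg_experiment(design, truth, seed = seed), paths$eggs)
  write_table_csv(simulate_life_history(design, truth, seed = seed + 1), paths$life)
  write_table_csv(simulate_monthly_raster(seed = seed + 2), paths$monthly)
  write_table_csv(simulate_daily_series(seed = seed + 3), paths$daily)
  jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full thermal-ecology analysis pipeline
#'
#' Wires the stages end to end: egg hatch-curve fits with minimal hatch
#' success, life-trait summaries and tests, thermal-performance model
#' selection with cardinal temperatures, the voltinism map driven by the
#' emergence-age fit plus the pre-oviposition shift, and the frost-event
#' count. Results are written as tidy CSV / JSON reports together with a
#' manifest recording the seed and an MD5 hash of every input.
#'
#' @param config A named list: `egg_records`, `life_records`,
#'   `monthly_raster`, `daily_series` (input CSV paths — all must exist),
#'   `out_dir` (created), `seed`, and optional `shift_days` (default 14),
#'   `min_hatch_temps` (temperatures to curve-fit; default all below
#'   5 degrees C) and `frost_threshold` / `frost_min_run_days`.
#' @return Invisibly, a list with every stage result (`hatch_fits`,
#'   `minimal_hatch`, `mortality`, `tests`, `tpc`, `zoo`, `gen_time`,
#'   `voltinism`, `frost`) and the `manifest`.
#' @export
run_thermal_pipeline <- function(config) {
  required <- c("egg_records", "life_records", "monthly_raster", "daily_series",
                "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config error: missing entries ", paste(missing, collapse = ", "))
  }
  inputs <- unlist(config[c("egg_records", "life_records", "monthly_raster",
                            "daily_series")])
  absent <- inputs[!file.exists(inputs)]
  if (length(absent)) {
    stop("config error: input path(s) do not exist: ",
         paste(absent, collapse = ", "))
  }
  seed <- config$seed %||% 1L
  shift <- config$shift_days %||% 14
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  eggs <- read_egg_records(config$egg_records)
  life <- read_life_records(config$life_records)
  monthly <- read_monthly_raster(config$monthly_raster)
  daily <- read_daily_series(config$daily_series)

  # egg stage: fit curves at the freezing treatments
  fit_temps <- config$min_hatch_temps %||%
    sort(unique(eggs$temperature_C[eggs$temperature_C < 5]))
  hatch_fits <- purrr::map(fit_temps, function(t) {
    fit_hatch_curve(dplyr::filter(eggs, .data$temperature_C == t))
  })
  names(hatch_fits) <- as.character(fit_temps)
  min_hatch <- tibble::tibble(
    temperature_C = fit_temps,
    family = purrr::map_chr(hatch_fits, "family"),
    minimal_hatch_pct = purrr::map_int(hatch_fits, minimal_hatch)
  )

  # life traits
  mortality <- mortality_table(life)
  tests <- list(
    mortality_anova = mortality_anova(life),
    sex_ratio = sex_ratio_test(life)
  )

  # thermal performance
  tpc <- build_tpc_points(life)
  zoo <- fit_model_zoo(tpc)

  # voltinism
  em_fit <- fit_age_curve(life, trait = "emergence")
  gmodel <- gen_time_from_emergence(em_fit, shift_days = shift)
  volt <- voltinism_map(monthly, gmodel)

  # frost
  frost <- count_frost_events(daily,
                              threshold = config$frost_threshold %||% 0,
                              min_run_days = config$frost_min_run_days %||% 3)

  # reports
  out <- config$out_dir
  write_table_csv(min_hatch, file.path(out, "minimal_hatch.csv"))
  write_table_csv(mortality, file.path(out, "mortality_table.csv"))
  write_table_csv(tests$sex_ratio, file.path(out, "sex_ratio_tests.csv"))
  write_table_csv(tpc, file.path(out, "tpc_points.csv"))
  write_table_csv(dplyr::select(zoo$report, -"estimates"),
                  file.path(out, "model_selection.csv"))
  write_table_csv(volt, file.path(out, "voltinism_map.csv"))
  write_table_csv(frost, file.path(out, "frost_summary.csv"))
  report <- list(
    seed = seed,
    cardinal_temperatures = if (!is.null(zoo$briere)) {
      as.list(cardinal_temperatures(zoo$briere))
    },
    best_tpc_model = zoo$best,
    generation_time_model = unclass(gmodel),
    voltinism_summary = as.list(attr(volt, "summary")),
    frost_events_per_year = frost$events_per_year
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- tibble::tibble(
    input = names(inputs), path = unname(inputs),
    md5 = unname(tools::md5sum(unname(inputs)))
  )
  write_table_csv(manifest, file.path(out, "manifest.csv"))

  invisible(list(hatch_fits = hatch_fits, minimal_hatch = min_hatch,
                 mortality = mortality, tests = tests, tpc = tpc, zoo = zoo,
                 gen_time = gmodel, voltinism = volt, frost = frost,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
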