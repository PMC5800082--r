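#' Experimental design description
#'
#' Collects the dimensions of the rearing and cold-exposure experiments
#' the generator emulates. Defaults reproduce the study layout: 16 larval
#' rearing temperatures with 5 cups of 40 larvae each, and egg cold
#' exposure at 4 temperatures x 10 durations x 5 cups of 20 eggs.
#'
#' @param temperatures_C Larval rearing water temperatures (degrees C).
#' @param cups_per_treatment Replicate cups per treatment cell.
#' @param larvae_per_cup Larvae per cup in the life-history experiment.
#' @param eggs_per_cup Eggs per cup in the cold-exposure experiment.
#' @param egg_temperatures_C Cold-exposure temperatures (degrees C).
#' @param exposure_durations_days Exposure durations in days; hour-scale
#'   exposures are fractional days (6 h = 0.25 d).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(
    temperatures_C = c(0, 5, 10, 12, 14, 15, 17, 19, 20, 23, 25, 26, 27, 28, 29, 31),
    cups_per_treatment = 5,
    larvae_per_cup = 40,
    eggs_per_cup = 20,
    egg_temperatures_C = c(5, 0, -5, -9),
    exposure_durations_days = c(0, 0.25, 0.5, 0.75, 1, 2, 3, 4, 7, 14)) {
  stopifnot(cups_per_treatment > 0, larvae_per_cup > 0, eggs_per_cup > 0,
            all(exposure_durations_days >= 0),
            all(is.finite(temperatures_C)), all(is.finite(egg_temperatures_C)))
  structure(list(
    temperatures_C = temperatures_C,
    cups_per_treatment = as.integer(cups_per_treatment),
    larvae_per_cup = as.integer(larvae_per_cup),
    eggs_per_cup = as.integer(eggs_per_cup),
    egg_temperatures_C = egg_temperatures_C,
    exposure_durations_days = exposure_durations_days
  ), class = "experiment_design")
}

#' Ground-truth parameters for the synthetic-data generator
#'
#' The generative twins of every fitted quantity in the analysis. Defaults
#' are the fitted study values: the Briere-1 thermal performance
#' parameters, the cold-exposure hatch curves at 0, -5 and -9 degrees C
#' (5 degrees C is a flat high-hatch control), and the exponential
#' age-vs-temperature curves (the emergence curve equals the
#' generation-time curve minus the 14-day pre-oviposition shift).
#'
#' @param briere List `a`, `m`, `t_min`, `t_max` of the performance curve.
#' @param hatch_curves Named list (names = exposure temperature as
#'   character) of hatch curves, each either
#'   `list(family = "exponential", A, k, c)` for `A e^{-kx} + c` or
#'   `list(family = "logistic", L, B, r)` for `L / (1 + B e^{rx})`
#'   (percent scale).
#' @param age_curves Named list with entries `pupation`, `emergence`,
#'   `adult_death`, each `list(A, k, c)` of `age = A e^{-kT} + c` days.
#'   Curves must be strictly ordered pupation < emergence < adult_death.
#' @param size List `female_mm_at_15C`, `slope_mm_per_C` (negative:
#'   smaller at warmer temperatures), `male_offset_mm`.
#' @param sex_ratio_p Probability an emerging adult is female.
#' @param noise List `age_cv` (lognormal coefficient of variation for
#'   ages) and `size_cv` (for wing length); hatch and survival noise is
#'   binomial and has no free parameter.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(
    briere = list(a = 6e-6, m = 2, t_min = 7, t_max = 31),
    hatch_curves = list(
      `5`  = list(family = "exponential", A = 0, k = 0, c = 87),
      `0`  = list(family = "exponential", A = 32.94, k = 0.41, c = 36.12),
      `-5` = list(family = "exponential", A = 74.01, k = 0.22, c = 10.67),
      `-9` = list(family = "logistic", L = 7.56e8, B = 7.25e8, r = 2.5621)
    ),
    age_curves = list(
      pupation = list(A = 240, k = 0.17, c = 5.8),
      emergence = list(A = 290.75, k = 0.17, c = 8.32),
      adult_death = list(A = 360, k = 0.17, c = 20)
    ),
    size = list(female_mm_at_15C = 4.26, slope_mm_per_C = -0.07625,
                male_offset_mm = -0.4),
    sex_ratio_p = 0.5,
    noise = list(age_cv = 0.1, size_cv = 0.05)) {
  stopifnot(briere$t_min < briere$t_max, briere$a > 0, briere$m > 0,
            sex_ratio_p > 0, sex_ratio_p < 1,
            noise$age_cv >= 0, noise$size_cv >= 0)
  for (hc in hatch_curves) {
    if (hc$family == "exponential") stopifnot(hc$c >= 0, hc$c <= 100)
  }
  structure(list(briere = briere, hatch_curves = hatch_curves,
                 age_curves = age_curves, size = size,
                 sex_ratio_p = sex_ratio_p, noise = noise),
            class = "ground_truth")
}

# evaluate a truth hatch curve (percent) at durations x
eval_hatch_curve <- function(curve, x) {
  if (curve$family == "exponential") {
    hatch_exponential(x, curve$A, curve$k, curve$c)
  } else {
    hatch_logistic(x, curve$L, curve$B, curve$r)
  }
}

eval_age_curve <- function(curve, temp_C) {
  curve$A * exp(-curve$k * temp_C) + curve$c
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate the egg cold-exposure experiment
#'
#' For every (temperature, duration, cup) cell, draws the number of
#' hatched larvae as Binomial(eggs per cup, truth curve / 100), the truth
#' probability clamped to `[0, 1]`.
#'
#' @param design An [experiment_design()].
#' @param truth A [ground_truth()]; its `hatch_curves` must cover every
#'   temperature in `design$egg_temperatures_C` and evaluate inside
#'   `[0, 100]` percent at every design duration.
#' @param seed Integer RNG seed; fixing it makes the output
#'   bit-reproducible.
#' @return A tibble of egg exposure records: `temperature_C`,
#'   `exposure_days`, `cup_id`, `n_eggs`, `n_hatched`.
#' @export
simulate_egg_experiment <- function(design = experiment_design(),
                                    truth = ground_truth(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"), inherits(truth, "ground_truth"))
  missing <- setdiff(as.character(design$egg_temperatures_C),
                     names(truth$hatch_curves))
  if (length(missing)) {
    stop("no truth hatch curve for temperature(s): ", paste(missing, collapse = ", "))
  }
  cells <- tidyr::expand_grid(
    temperature_C = design$egg_temperatures_C,
    exposure_days = design$exposure_durations_days,
    cup_id = seq_len(design$cups_per_treatment)
  )
  p <- purrr::map2_dbl(cells$temperature_C, cells$exposure_days, function(tt, x) {
    eval_hatch_curve(truth$hatch_curves[[as.character(tt)]], x)
  })
  if (any(p < -1e-9 | p > 100 + 1e-9)) {
    stop("truth hatch curve evaluates outside [0, 100] percent; rejecting parameters")
  }
  p <- pmin(pmax(p / 100, 0), 1)
  withr::local_seed(seed)
  cells$n_eggs <- design$eggs_per_cup
  cells$n_hatched <- stats::rbinom(nrow(cells), design$eggs_per_cup, p)
  tibble::as_tibble(cells)
}

# survival probability implied by the truth: performance divided by the
# female developmental rate (i.e. briere * emergence age), clamped to [0, 1]
truth_survival <- function(truth, temp_C) {
  perf <- briere1(temp_C, truth$briere$a, truth$briere$m,
                  truth$briere$t_min, truth$briere$t_max)
  em <- eval_age_curve(truth$age_curves$emergence, temp_C)
  pmin(pmax(perf * em, 0), 1)
}

#' Simulate the larval life-history experiment
#'
#' Draws per-individual fates so that, in expectation, the product of
#' survival and female developmental rate reproduces the truth Briere-1
#' performance curve: survival is the performance curve divided by the
#' developmental rate (clamped to `[0, 1]`), and ages are the truth
#' exponential curves with multiplicative lognormal noise. Survivor ages
#' are strictly ordered pupation < emergence < death (noise is applied to
#' the pupation age and to the positive stage gaps); non-survivors carry a
#' death age only. Temperatures outside the Briere limits yield no
#' survivors by construction.
#'
#' @inheritParams simulate_egg_experiment
#' @return A tibble of individual records: `temperature_C`, `cup_id`,
#'   `individual`, `survived`, `sex` ("female"/"male" for survivors,
#'   "unknown" otherwise), `age_pupation_days`, `age_emergence_days`,
#'   `age_death_days`, `r1_mm`.
#' @export
simulate_life_history <- function(design = experiment_design(),
                                  truth = ground_truth(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"), inherits(truth, "ground_truth"))
  tg <- design$temperatures_C
  pup <- vapply(tg, function(t) eval_age_curve(truth$age_curves$pupation, t), 1)
  em <- vapply(tg, function(t) eval_age_curve(truth$age_curves$emergence, t), 1)
  dth <- vapply(tg, function(t) eval_age_curve(truth$age_curves$adult_death, t), 1)
  if (any(pup >= em) || any(em >= dth)) {
    stop("truth age curves must satisfy pupation < emergence < adult_death at all design temperatures")
  }
  withr::local_seed(seed)
  cv <- truth$noise$age_cv
  recs <- purrr::map_dfr(seq_along(tg), function(i) {
    t <- tg[i]
    n <- design$cups_per_treatment * design$larvae_per_cup
    surv_p <- truth_survival(truth, t)
    survived <- stats::rbinom(n, 1, surv_p) == 1
    sex <- ifelse(survived,
                  ifelse(stats::runif(n) < truth$sex_ratio_p, "female", "male"),
                  "unknown")
    age_pup <- ifelse(survived, pup[i] * rlnorm_mean1(n, cv), NA_real_)
    age_em <- ifelse(survived, age_pup + (em[i] - pup[i]) * rlnorm_mean1(n, cv),
                     NA_real_)
    age_dth <- ifelse(survived, age_em + (dth[i] - em[i]) * rlnorm_mean1(n, cv),
                      stats::runif(n, 1, max(em[i], 3)))
    r1_mean <- truth$size$female_mm_at_15C +
      truth$size$slope_mm_per_C * (t - 15) +
      ifelse(sex == "male", truth$size$male_offset_mm, 0)
    r1 <- ifelse(survived, pmax(r1_mean, 0.5) * rlnorm_mean1(n, truth$noise$size_cv),
                 NA_real_)
    tibble::tibble(
      temperature_C = t,
      cup_id = rep(seq_len(design$cups_per_treatment),
                   each = design$larvae_per_cup),
      individual = seq_len(n),
      survived = survived,
      sex = sex,
      age_pupation_days = age_pup,
      age_emergence_days = age_em,
      age_death_days = age_dth,
      r1_mm = r1
    )
  })
  recs
}

#' Simulate a monthly mean temperature grid
#'
#' A regular lon/lat grid with a smooth seasonal cycle per cell: the
#' annual mean falls off with latitude, the cycle is sinusoidal with its
#' peak in July, and cell-level noise is spatially independent. Values
#' are clamped to `[-20, 40]` degrees C.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)`; default a
#'   Germany-like window.
#' @param resolution Cell size in degrees.
#' @param mean_C Annual mean temperature at the southern edge.
#' @param amplitude_C Half peak-to-trough seasonal amplitude.
#' @param lat_gradient_C Cooling per degree of latitude northwards.
#' @param noise_sd Cell-level standard deviation of the annual mean
#'   (degrees C).
#' @param seed Integer RNG seed.
#' @return A long tibble: `x`, `y` (cell centres), `month` (1-12),
#'   `temp_C`.
#' @export
simulate_monthly_raster <- function(extent = c(6, 15, 47.5, 55),
                                    resolution = 0.5,
                                    mean_C = 9, amplitude_C = 9,
                                    lat_gradient_C = 0.4, noise_sd = 0.5,
                                    seed = 1L) {
  stopifnot(length(extent) == 4, extent[1] < extent[2], extent[3] < extent[4],
            resolution > 0)
  xs <- seq(extent[1] + resolution / 2, extent[2], by = resolution)
  ys <- seq(extent[3] + resolution / 2, extent[4], by = resolution)
  cells <- tidyr::expand_grid(x = xs, y = ys)
  withr::local_seed(seed)
  cells$cell_mean <- mean_C - lat_gradient_C * (cells$y - extent[3]) +
    stats::rnorm(nrow(cells), 0, noise_sd)
  out <- tidyr::expand_grid(cells, month = 1:12)
  out$temp_C <- out$cell_mean + amplitude_C * cos(2 * pi * (out$month - 7) / 12)
  out$temp_C <- pmin(pmax(out$temp_C, -20), 40)
  dplyr::select(out, "x", "y", "month", "temp_C")
}

#' Simulate a daily mean temperature series
#'
#' A seasonal sinusoid plus AR(1) noise, one value per day for
#' `365 * n_years` consecutive days (no leap-day handling: the day count
#' is exactly 365 per year).
#'
#' @param n_years Number of years.
#' @param mean_C Annual mean temperature.
#' @param amplitude_C Seasonal half-amplitude.
#' @param ar Lag-1 autocorrelation of the noise.
#' @param sd_C Marginal standard deviation of the noise (degrees C).
#' @param start_date First day of the series.
#' @param seed Integer RNG seed.
#' @return A tibble: `date`, `temp_C`.
#' @export
simulate_daily_series <- function(n_years = 10, mean_C = 9, amplitude_C = 10,
                                  ar = 0.7, sd_C = 3,
                                  start_date = as.Date("2001-01-01"),
                                  seed = 1L) {
  stopifnot(n_years > 0, abs(ar) < 1, sd_C >= 0)
  n <- 365L * as.integer(n_years)
  doy <- (seq_len(n) - 1) %% 365
  seasonal <- mean_C - amplitude_C * cos(2 * pi * (doy - 15) / 365)
  withr::local_seed(seed)
  innov_sd <- sd_C * sqrt(1 - ar^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar,
                                    method = "recursive"))
  tibble::tibble(date = start_date + seq_len(n) - 1, temp_C = seasonal + noise)
}

#' Simulate a daily temperature grid
#'
#' One [simulate_daily_series()] per grid cell, with the annual mean
#' falling off with latitude; used to exercise [frost_map()].
#'
#' @inheritParams simulate_monthly_raster
#' @inheritParams simulate_daily_series
#' @return A long tibble: `x`, `y`, `date`, `temp_C`.
#' @export
simulate_daily_grid <- function(extent = c(6, 15, 47.5, 55), resolution = 3,
                                n_years = 3, mean_C = 9, amplitude_C = 10,
                                lat_gradient_C = 0.4, ar = 0.7, sd_C = 3,
                                seed = 1L) {
  xs <- seq(extent[1] + resolution / 2, extent[2], by = resolution)
  ys <- seq(extent[3] + resolution / 2, extent[4], by = resolution)
  cells <- tidyr::expand_grid(x = xs, y = ys)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    s <- simulate_daily_series(
      n_years = n_years,
      mean_C = mean_C - lat_gradient_C * (cells$y[i] - extent[3]),
      amplitude_C = amplitude_C, ar = ar, sd_C = sd_C,
      seed = seed + i
    )
    tibble::tibble(x = cells$x[i], y = cells$y[i], date = s$date,
                   temp_C = s$temp_C)
  })
}
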