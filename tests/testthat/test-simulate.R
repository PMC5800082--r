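test_that("simulators are bit-reproducible under a fixed seed", {
  expect_identical(simulate_egg_experiment(seed = 11),
                   simulate_egg_experiment(seed = 11))
  expect_identical(simulate_life_history(seed = 11),
                   simulate_life_history(seed = 11))
  expect_identical(simulate_monthly_raster(seed = 11),
                   simulate_monthly_raster(seed = 11))
  expect_identical(simulate_daily_series(n_years = 2, seed = 11),
                   simulate_daily_series(n_years = 2, seed = 11))
  expect_false(identical(simulate_egg_experiment(seed = 11)$n_hatched,
                         simulate_egg_experiment(seed = 12)$n_hatched))
})

test_that("degenerate hatch curves give all-or-nothing hatch", {
  d <- experiment_design(egg_temperatures_C = c(0, -5))
  truth_all <- ground_truth(hatch_curves = list(
    `0` = list(family = "exponential", A = 0, k = 0, c = 100),
    `-5` = list(family = "exponential", A = 0, k = 0, c = 0)
  ))
  eggs <- simulate_egg_experiment(d, truth_all, seed = 1)
  expect_true(all(eggs$n_hatched[eggs$temperature_C == 0] == eggs$n_eggs[1]))
  expect_true(all(eggs$n_hatched[eggs$temperature_C == -5] == 0))
})

test_that("truth hatch curves outside [0, 100] percent are rejected", {
  d <- experiment_design(egg_temperatures_C = 0)
  bad <- ground_truth(hatch_curves = list(
    `0` = list(family = "exponential", A = 80, k = 0.1, c = 40)  # 120% at x = 0
  ))
  expect_error(simulate_egg_experiment(d, bad, seed = 1), "outside")
})

test_that("empirical hatch fraction converges to the truth curve", {
  # 1000 cups at one cell; agreement within 3 binomial standard errors
  d <- experiment_design(egg_temperatures_C = 0, exposure_durations_days = 0,
                         cups_per_treatment = 1000)
  eggs <- simulate_egg_experiment(d, ground_truth(), seed = 5)
  p_true <- curve_0C(0) / 100  # 0.6906
  phat <- mean(eggs$n_hatched / eggs$n_eggs)
  se <- sqrt(p_true * (1 - p_true) / (1000 * 20))
  expect_lt(abs(phat - p_true), 3 * se)
})

test_that("empirical mortality matches one minus the truth survival", {
  d <- experiment_design(temperatures_C = c(0, 20, 25, 26),
                         cups_per_treatment = 25, larvae_per_cup = 40)
  truth <- ground_truth()
  lh <- simulate_life_history(d, truth, seed = 9)
  for (t in d$temperatures_C) {
    sub <- lh[lh$temperature_C == t, ]
    s_true <- briere1(t, 6e-6, 2, 7, 31) * (290.75 * exp(-0.17 * t) + 8.32)
    s_true <- min(max(s_true, 0), 1)
    se <- sqrt(max(s_true * (1 - s_true), 1e-6) / nrow(sub))
    expect_lt(abs(mean(sub$survived) - s_true), max(3 * se, 1e-12))
  }
})

test_that("no adults emerge outside the developmental limits", {
  lh <- simulate_life_history(seed = 2)
  expect_equal(sum(lh$survived[lh$temperature_C %in% c(0, 5)]), 0)
})

test_that("survivor ages are strictly ordered and sexes near balance", {
  d <- experiment_design(temperatures_C = c(23, 25, 26),
                         cups_per_treatment = 40)
  lh <- simulate_life_history(d, ground_truth(), seed = 8)
  sv <- lh[lh$survived, ]
  expect_gt(nrow(sv), 100)
  expect_true(all(sv$age_pupation_days < sv$age_emergence_days))
  expect_true(all(sv$age_emergence_days < sv$age_death_days))
  expect_true(all(is.na(lh$age_pupation_days[!lh$survived])))
  expect_true(all(!is.na(lh$age_death_days[!lh$survived])))
  # law of large numbers on the sex ratio
  expect_lt(abs(mean(sv$sex == "female") - 0.5), 3 * sqrt(0.25 / nrow(sv)))
})

test_that("mean simulated emergence age tracks the truth curve at 25 C", {
  d <- experiment_design(temperatures_C = 25, cups_per_treatment = 60)
  lh <- simulate_life_history(d, ground_truth(), seed = 4)
  sv <- lh[lh$survived, ]
  truth_age <- g_curve(25) - 14  # 12.47 d
  cv <- 0.1
  se <- truth_age * cv / sqrt(nrow(sv))
  expect_lt(abs(mean(sv$age_emergence_days) - truth_age), 4 * se)
})

test_that("monthly raster has 12 bands per cell, a seasonal cycle, bounded values", {
  r <- simulate_monthly_raster(seed = 3)
  counts <- dplyr::count(r, x, y)
  expect_true(all(counts$n == 12))
  expect_true(all(r$temp_C >= -20 & r$temp_C <= 40))
  july <- r$temp_C[r$month == 7]
  jan <- r$temp_C[r$month == 1]
  expect_true(all(july > jan))
})

test_that("daily series has 365 days per year and a winter minimum", {
  s <- simulate_daily_series(n_years = 3, seed = 6)
  expect_equal(nrow(s), 3 * 365)
  expect_equal(as.integer(diff(range(s$date))), 3 * 365 - 1)
  by_month <- tapply(s$temp_C, format(s$date, "%m"), mean)
  expect_lt(by_month[["01"]], by_month[["07"]])
})
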