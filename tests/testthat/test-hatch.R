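test_that("mean hatch success averages per-cup percentages", {
  rec <- egg_records(list(`0@0` = c(20, 20, 20, 20, 20),
                          `0@1` = c(10, 10, 10, 10, 10)))
  ms <- mean_hatch_success(rec)
  expect_equal(ms$mean_hatch_pct, c(100, 50))
  expect_equal(ms$n_cups, c(5L, 5L))
  # mean of percentages, not pooled counts: unequal cup sizes
  rec2 <- tibble::tibble(temperature_C = 0, exposure_days = 0, cup_id = 1:2,
                         n_eggs = c(10, 40), n_hatched = c(10, 0))
  expect_equal(mean_hatch_success(rec2)$mean_hatch_pct, 50)
})

test_that("noiseless exponential series recovers the generating coefficients", {
  fit <- fit_hatch_curve(noiseless_series(curve_0C))
  expect_equal(fit$family, "exponential")
  expect_equal(unname(fit$coefficients[c("A", "k", "c")]),
               c(32.94, 0.41, 36.12), tolerance = 1e-3)
  fit5 <- fit_hatch_curve(noiseless_series(curve_m5C))
  expect_equal(unname(fit5$coefficients[c("A", "k", "c")]),
               c(74.01, 0.22, 10.67), tolerance = 1e-3)
})

test_that("noiseless logistic series selects the logistic family", {
  fit <- fit_hatch_curve(noiseless_series(curve_m9C))
  expect_equal(fit$family, "logistic")
  expect_gt(fit$coefficients[["r"]], 0)
  expect_equal(minimal_hatch(fit), 0L)
  # the fitted curve matches the generating one on a fine grid
  grid <- tibble::tibble(exposure_days = seq(0, 14, by = 0.1))
  expect_equal(predict(fit, grid), curve_m9C(grid$exposure_days),
               tolerance = 1e-4)
})

test_that("constant hatch series is flagged degenerate with the mean as asymptote", {
  series <- tibble::tibble(exposure_days = study_durations, mean_hatch_pct = 80)
  expect_warning(fit <- fit_hatch_curve(series), "unidentifiable")
  expect_true(fit$degenerate)
  expect_equal(fit$minimal_hatch_pct, 80)
})

test_that("minimal hatch truncates the asymptote to whole percent", {
  fit0 <- fit_hatch_curve(noiseless_series(curve_0C))
  fit5 <- fit_hatch_curve(noiseless_series(curve_m5C))
  expect_identical(minimal_hatch(fit0), 36L)  # 36.12 -> 36
  expect_identical(minimal_hatch(fit5), 10L)  # 10.67 -> 10
})

test_that("minimal hatch is invariant to duration-unit rescaling", {
  days <- noiseless_series(curve_0C)
  hours <- dplyr::mutate(days, exposure_days = exposure_days * 24)
  f_days <- fit_hatch_curve(days)
  f_hours <- fit_hatch_curve(hours)
  expect_equal(f_days$minimal_hatch_pct, f_hours$minimal_hatch_pct,
               tolerance = 1e-6)
})

test_that("AIC selection recovers the generating family in most replicates", {
  d <- experiment_design(egg_temperatures_C = c(0, -5))
  fams <- vapply(1:200, function(i) {
    eggs <- simulate_egg_experiment(d, ground_truth(), seed = 20000 + i)
    sub <- eggs[eggs$temperature_C == 0, ]
    suppressWarnings(fit_hatch_curve(sub)$family)
  }, character(1))
  expect_gte(mean(fams == "exponential"), 0.9)
})

test_that("fitted exponential coefficients are unbiased under binomial noise", {
  d <- experiment_design(egg_temperatures_C = 0)
  cf <- vapply(1:200, function(i) {
    eggs <- simulate_egg_experiment(d, ground_truth(), seed = 30000 + i)
    f <- suppressWarnings(
      fit_hatch_curve(eggs[eggs$temperature_C == 0, ], family = "exponential"))
    f$coefficients[c("A", "k", "c")]
  }, numeric(3))
  truth <- c(A = 32.94, k = 0.41, c = 36.12)
  for (p in rownames(cf)) {
    mc_se <- stats::sd(cf[p, ]) / sqrt(ncol(cf))
    expect_lt(abs(mean(cf[p, ]) - truth[[p]]), 3 * mc_se + 0.02 * truth[[p]])
  }
})

test_that("exposure-length effect test matches its design", {
  # identical hatch at all durations: no effect
  flat <- egg_records(stats::setNames(
    lapply(study_durations, function(x) rep(16, 5)),
    paste0("5@", study_durations)))
  res <- exposure_effect_test(flat)
  expect_equal(res$value, 0)
  expect_equal(res$p, 1)
  expect_equal(c(res$df1, res$df2), c(1, 8))
  # strong monotone decline: clearly significant
  withr::with_seed(1, {
    decline <- egg_records(stats::setNames(
      lapply(study_durations, function(x) {
        stats::rbinom(5, 20, max(0.95 - 0.06 * x, 0.05))
      }),
      paste0("0@", study_durations)))
  })
  expect_lt(exposure_effect_test(decline)$p, 0.05)
  # flat but noisy (5 C-like): no effect
  withr::with_seed(2, {
    noisy <- egg_records(stats::setNames(
      lapply(study_durations, function(x) stats::rbinom(5, 20, 0.85)),
      paste0("5@", study_durations)))
  })
  expect_gt(exposure_effect_test(noisy)$p, 0.05)
  # cross-check against a from-scratch regression F on one fixture
  ms <- mean_hatch_success(decline)
  y <- asin(sqrt(ms$mean_hatch_pct / 100))
  x <- ms$exposure_days
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  rss1 <- sum((y - a - b * x)^2)
  rss0 <- sum((y - mean(y))^2)
  F_manual <- (rss0 - rss1) / (rss1 / (length(y) - 2))
  expect_equal(exposure_effect_test(decline)$value, F_manual, tolerance = 1e-8)
})

test_that("hatch fit tidiers and plot expose the right pieces", {
  fit <- fit_hatch_curve(noiseless_series(curve_0C))
  td <- tidy(fit)
  expect_setequal(td$term, c("A", "k", "c"))
  gl <- glance(fit)
  expect_equal(gl$family, "exponential")
  expect_s3_class(autoplot(fit), "ggplot")
})
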