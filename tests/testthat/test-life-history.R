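test_that("mortality table reproduces constructed per-cup means", {
  # all dead
  all_dead <- mortality_records(0, rep(40, 5))
  tab <- mortality_table(all_dead)
  expect_equal(tab$mean_mortality_pct, 100)
  expect_equal(tab$sd_pct, 0)
  # equal cups: mean 10, sd 0
  tab2 <- mortality_table(mortality_records(20, rep(4, 5)))
  expect_equal(tab2$mean_mortality_pct, 10)
  expect_equal(tab2$sd_pct, 0)
  # 26 C-like cell: per-cup deaths averaging 6%
  tab3 <- mortality_table(mortality_records(26, c(2, 2, 3, 2, 3)))
  expect_equal(tab3$mean_mortality_pct, 6)
})

test_that("mortality summaries are scale-invariant to cup size", {
  small <- mortality_records(20, c(2, 4, 6, 8, 10), larvae_per_cup = 20)
  large <- mortality_records(20, c(4, 8, 12, 16, 20), larvae_per_cup = 40)
  expect_equal(mortality_table(small)$mean_mortality_pct,
               mortality_table(large)$mean_mortality_pct)
  expect_equal(mortality_table(small)$sd_pct, mortality_table(large)$sd_pct)
})

test_that("mortality ANOVA matches a from-scratch F computation", {
  withr::with_seed(42, {
    recs <- dplyr::bind_rows(
      mortality_records(10, rbinom(5, 40, 0.1)),
      mortality_records(20, rbinom(5, 40, 0.5)),
      mortality_records(30, rbinom(5, 40, 0.9))
    )
  })
  res <- mortality_anova(recs)
  cups <- recs |>
    dplyr::group_by(temperature_C, cup_id) |>
    dplyr::summarise(m = 1 - mean(survived), .groups = "drop")
  oracle <- manual_anova_F(asin(sqrt(cups$m)), cups$temperature_C)
  expect_equal(res$value, oracle$F, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(oracle$df1, oracle$df2))
})

test_that("identical groups give F near 0 and strongly separated groups reject", {
  same <- dplyr::bind_rows(mortality_records(10, c(4, 5, 6, 5, 4)),
                           mortality_records(20, c(4, 5, 6, 5, 4)))
  expect_gt(mortality_anova(same)$p, 0.9)
  withr::with_seed(7, {
    apart <- dplyr::bind_rows(
      mortality_records(10, pmax(pmin(round(rnorm(5, 4, 0.8)), 40), 0)),
      mortality_records(30, pmax(pmin(round(rnorm(5, 36, 0.8)), 40), 0))
    )
  })
  pt <- pairwise_t(apart)
  expect_lt(pt$p[1], 0.001)
})

test_that("pairwise t-tests apply Bonferroni over the number of pairs", {
  withr::with_seed(3, {
    recs <- dplyr::bind_rows(lapply(c(10, 15, 20, 25, 30), function(t) {
      mortality_records(t, rbinom(5, 40, 0.3))
    }))
  })
  pt <- pairwise_t(recs)
  expect_equal(nrow(pt), choose(5, 2))
  expect_equal(pt$p, pmin(pt$p_raw * choose(5, 2), 1))
  raw <- pairwise_t(recs, adjust = "none")
  expect_equal(raw$p, raw$p_raw)
})

test_that("sex ratio test is the exact two-sided binomial test", {
  mk <- function(nf, nm, t = 25) {
    tibble::tibble(temperature_C = t,
                   sex = rep(c("female", "male"), c(nf, nm)),
                   survived = TRUE)
  }
  expect_equal(sex_ratio_test(mk(10, 10))$p, 1)
  expect_equal(sex_ratio_test(mk(0, 20))$p, 2 * 0.5^20, tolerance = 1e-12)
  # exact-sum oracle for 35 females / 15 males
  dens <- dbinom(0:50, 50, 0.5)
  p_oracle <- sum(dens[dens <= dbinom(35, 50, 0.5) * (1 + 1e-7)])
  expect_equal(sex_ratio_test(mk(35, 15))$p, p_oracle, tolerance = 1e-10)
  # pooled over cups, not per-cup
  two <- dplyr::bind_rows(mk(35, 15), mk(0, 0))
  expect_equal(nrow(sex_ratio_test(two)), 1)
})

test_that("noiseless age means recover the exponential curve and flag degeneracy", {
  temps <- c(10, 14, 17, 20, 23, 26, 29, 31)
  recs <- tibble::tibble(
    temperature_C = rep(temps, each = 3), cup_id = 1, survived = TRUE,
    age_emergence_days = rep(290.75 * exp(-0.17 * temps) + 8.32, each = 3)
  )
  fit <- fit_age_curve(recs, trait = "emergence")
  expect_equal(unname(fit$coefficients[c("A", "k", "c")]),
               c(290.75, 0.17, 8.32), tolerance = 1e-3)
  # emergence at 25 C from that curve is ~12.5 d
  expect_equal(predict(fit, tibble::tibble(temperature_C = 25)), 12.47,
               tolerance = 1e-2)
  const <- dplyr::mutate(recs, age_emergence_days = 20)
  expect_warning(cf <- fit_age_curve(const, trait = "emergence"), "constant")
  expect_true(cf$degenerate)
  expect_error(fit_age_curve(recs[recs$temperature_C < 15, ], "emergence"),
               ">= 4 temperatures")
})

test_that("temperature explains most of the age variance on generated fixtures", {
  lh <- simulate_life_history(seed = 21)
  sv <- lh[lh$survived, ]
  fit <- stats::aov(age_emergence_days ~ factor(temperature_C), data = sv)
  s <- summary(fit)[[1]]
  r2 <- s$`Sum Sq`[1] / sum(s$`Sum Sq`)
  expect_gt(r2, 0.8)
})

test_that("size summary and two-way ANOVA behave as designed", {
  withr::with_seed(5, {
    grid <- tidyr::expand_grid(temperature_C = c(15, 23, 31),
                               sex = c("female", "male"), rep = 1:30)
    # proportional sex dimorphism: zero sex effect on the percent scale
    truth_mm <- (4.26 - 0.07625 * (grid$temperature_C - 15)) *
      ifelse(grid$sex == "male", 0.9, 1)
    recs <- dplyr::mutate(grid, cup_id = 1, survived = TRUE,
                          r1_mm = truth_mm * exp(rnorm(nrow(grid), 0, 0.03)))
  })
  ss <- size_summary(recs)
  f15 <- ss$mean_R1_mm[ss$temperature_C == 15 & ss$sex == "female"]
  f31 <- ss$mean_R1_mm[ss$temperature_C == 31 & ss$sex == "female"]
  expect_equal(f15, 4.26, tolerance = 3 * 4.26 * 0.03 / sqrt(30))
  expect_equal(f31, 3.04, tolerance = 3 * 3.04 * 0.03 / sqrt(30))
  an <- size_anova(recs)
  expect_equal(an$term, c("temperature", "sex", "temperature:sex"))
  expect_lt(an$p[an$term == "temperature"], 0.001)
  expect_lt(an$p[an$term == "sex"], 0.001)
  # on the percent-difference-to-maximum scale the dimorphism is removed:
  # the sex F statistic collapses relative to the raw-length analysis
  an2 <- size_anova(recs, response = "pct_diff_max")
  expect_lt(an2$value[an2$term == "sex"],
            an$value[an$term == "sex"] / 20)
  expect_lt(an2$p[an2$term == "temperature"], 0.001)
  expect_error(size_anova(recs[recs$sex == "female", ]), "both sexes")
})

test_that("sex effect on the percent-difference scale stays null in most replicates", {
  # the per-sex reference maximum is itself estimated, which inflates the
  # sex term's type-I rate above nominal; ~3/4 retention is the level the
  # procedure supports regardless of sample size
  hits <- vapply(1:40, function(i) {
    withr::with_seed(600 + i, {
      grid <- tidyr::expand_grid(temperature_C = c(15, 23, 31),
                                 sex = c("female", "male"), rep = 1:15)
      truth_mm <- (4.26 - 0.07625 * (grid$temperature_C - 15)) *
        ifelse(grid$sex == "male", 0.9, 1)
      recs <- dplyr::mutate(grid, cup_id = 1, survived = TRUE,
                            r1_mm = truth_mm * exp(rnorm(nrow(grid), 0, 0.05)))
    })
    an <- size_anova(recs, response = "pct_diff_max")
    an$p[an$term == "sex"] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("emergence fit plus the pre-oviposition shift reproduces the G curve", {
  temps <- c(10, 12, 15, 17, 20, 23, 26, 29, 31)
  recs <- tibble::tibble(
    temperature_C = rep(temps, each = 2), cup_id = 1, survived = TRUE,
    age_emergence_days = rep(g_curve(temps) - 14, each = 2)
  )
  g <- gen_time_from_emergence(fit_age_curve(recs, "emergence"), shift_days = 14)
  expect_equal(g$A, 290.75, tolerance = 1e-4)
  expect_equal(g$k, 0.17, tolerance = 1e-4)
  expect_equal(g$c, 22.32, tolerance = 1e-4)
  grid <- seq(5, 35, by = 0.5)
  expect_equal(generation_time(grid, g), g_curve(grid), tolerance = 1e-4)
})
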