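# Shared fixture builders; everything is generated in code.

study_durations <- c(0, 0.25, 0.5, 0.75, 1, 2, 3, 4, 7, 14)
study_temperatures <- c(0, 5, 10, 12, 14, 15, 17, 19, 20, 23, 25, 26, 27, 28,
                        29, 31)

# published exposure-response curves (percent vs days)
curve_0C <- function(x) 32.94 * exp(-0.41 * x) + 36.12
curve_m5C <- function(x) 74.01 * exp(-0.22 * x) + 10.67
curve_m9C <- function(x) 7.56e8 / (1 + 7.25e8 * exp(2.5621 * x))

# published generation-time curve (days vs degrees C)
g_curve <- function(t) 290.75 * exp(-0.17 * t) + 22.32

# noiseless mean-hatch series on the study duration grid
noiseless_series <- function(f, x = study_durations) {
  tibble::tibble(exposure_days = x, mean_hatch_pct = f(x))
}

# per-cup egg records realising exact per-cup hatch counts
egg_records <- function(counts_by_cell, n_eggs = 20) {
  purrr::imap_dfr(counts_by_cell, function(counts, key) {
    parts <- as.numeric(strsplit(key, "@")[[1]])
    tibble::tibble(temperature_C = parts[1], exposure_days = parts[2],
                   cup_id = seq_along(counts), n_eggs = n_eggs,
                   n_hatched = counts)
  })
}

# life-history records realising exact per-cup death counts
mortality_records <- function(temp, deaths_per_cup, larvae_per_cup = 40) {
  purrr::map_dfr(seq_along(deaths_per_cup), function(cup) {
    d <- deaths_per_cup[cup]
    tibble::tibble(temperature_C = temp, cup_id = cup,
                   survived = rep(c(FALSE, TRUE), c(d, larvae_per_cup - d)),
                   sex = "unknown")
  })
}

# independent brute-force day scan: count maximal cold runs >= min_run
brute_force_frost <- function(temps, threshold = 0, min_run = 3) {
  count <- 0L
  run <- 0L
  for (v in temps) {
    if (!is.na(v) && v <= threshold) {
      run <- run + 1L
    } else {
      if (run >= min_run) count <- count + 1L
      run <- 0L
    }
  }
  if (run >= min_run) count <- count + 1L
  count
}

# every event interval of `inner` lies inside some event interval of `outer`
# (the monotonicity that actually holds under cooling or a raised threshold:
# cold days are a superset, so runs can only grow or merge, never vanish)
events_contained <- function(inner, outer) {
  inner_ev <- attr(inner, "events")
  outer_ev <- attr(outer, "events")
  if (nrow(inner_ev) == 0) return(TRUE)
  all(vapply(seq_len(nrow(inner_ev)), function(i) {
    any(outer_ev$start <= inner_ev$start[i] & outer_ev$end >= inner_ev$end[i])
  }, logical(1)))
}

# one-way ANOVA F computed from first principles (group sums)
manual_anova_F <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}
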