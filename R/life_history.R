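#' Per-temperature mortality summary
#'
#' Mortality is computed per cup (fraction of larvae that failed to reach
#' adulthood) and then averaged over the replicate cups of each temperature
#' treatment, so the summary matches cup-level standard deviations.
#'
#' @param records Individual life-history records: columns `temperature_C`,
#'   `cup_id`, `survived` (logical or 0/1).
#' @return A tibble with `temperature_C`, `n_cups`, `mean_mortality_pct`,
#'   `sd_pct`.
#' @export
mortality_table <- function(records) {
  check_columns(records, c("temperature_C", "cup_id", "survived"))
  records |>
    dplyr::group_by(.data$temperature_C, .data$cup_id) |>
    dplyr::summarise(mortality = 1 - mean(as.numeric(.data$survived)),
                     .groups = "drop") |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(
      n_cups = dplyr::n(),
      mean_mortality_pct = 100 * mean(.data$mortality),
      sd_pct = 100 * stats::sd(.data$mortality),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$temperature_C)
}

# per-cup arcsine-transformed mortality, the unit of analysis for the tests
cup_mortality <- function(records) {
  records |>
    dplyr::group_by(.data$temperature_C, .data$cup_id) |>
    dplyr::summarise(mortality = 1 - mean(as.numeric(.data$survived)),
                     .groups = "drop") |>
    dplyr::mutate(y = asin_sqrt(.data$mortality))
}

#' One-way ANOVA of mortality across temperature treatments
#'
#' Tests for differences in arcsine-square-root-transformed per-cup
#' mortality between temperature groups.
#'
#' @inheritParams mortality_table
#' @return A one-row tibble: `statistic` ("F"), `value`, `df1`, `df2`, `p`,
#'   `adjustment`.
#' @export
mortality_anova <- function(records) {
  dat <- cup_mortality(records)
  if (length(unique(dat$temperature_C)) < 2) {
    stop("mortality_anova needs at least two temperature groups")
  }
  fit <- stats::aov(y ~ factor(temperature_C), data = dat)
  s <- summary(fit)[[1]]
  tibble::tibble(statistic = "F", value = s$`F value`[1],
                 df1 = s$Df[1], df2 = s$Df[2], p = s$`Pr(>F)`[1],
                 adjustment = "none")
}

#' Pairwise t-tests of mortality between all temperature pairs
#'
#' Two-tailed Welch t-tests on arcsine-transformed per-cup mortality for
#' every pair of temperature treatments, with Bonferroni correction over
#' the number of pairs.
#'
#' @inheritParams mortality_table
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A tibble with one row per pair: `temperature_1`,
#'   `temperature_2`, `statistic`, `value`, `df`, `p_raw`, `p`,
#'   `adjustment`.
#' @export
pairwise_t <- function(records, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  dat <- cup_mortality(records)
  temps <- sort(unique(dat$temperature_C))
  if (length(temps) < 2) stop("need at least two temperature groups")
  pairs <- utils::combn(temps, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    t1 <- pairs[1, i]; t2 <- pairs[2, i]
    y1 <- dat$y[dat$temperature_C == t1]
    y2 <- dat$y[dat$temperature_C == t2]
    tt <- tryCatch(stats::t.test(y1, y2), error = function(e) NULL)
    tibble::tibble(
      temperature_1 = t1, temperature_2 = t2, statistic = "t",
      value = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p_raw = if (is.null(tt)) NA_real_ else tt$p.value
    )
  })
  m <- nrow(res)
  res$p <- if (adjust == "bonferroni") pmin(res$p_raw * m, 1) else res$p_raw
  res$adjustment <- adjust
  res
}

#' Exact binomial test of the adult sex ratio
#'
#' Tests the departure of emerged adults from an expected 1:1 sex ratio per
#' temperature treatment, pooling counts over replicate cups, with a
#' two-sided exact binomial test against p = 0.5.
#'
#' @param records Individual records with `temperature_C`, `sex`
#'   ("female"/"male"; others ignored) and `survived`.
#' @return A tibble with one row per temperature: `temperature_C`,
#'   `n_female`, `n_male`, `statistic` ("binomial"), `p`, `adjustment`.
#' @export
sex_ratio_test <- function(records) {
  check_columns(records, c("temperature_C", "sex", "survived"))
  records |>
    dplyr::filter(as.logical(.data$survived), .data$sex %in% c("female", "male")) |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(
      n_female = sum(.data$sex == "female"),
      n_male = sum(.data$sex == "male"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      statistic = "binomial",
      p = purrr::map2_dbl(.data$n_female, .data$n_female + .data$n_male,
                          function(x, n) {
                            if (n == 0) return(NA_real_)
                            stats::binom.test(x, n, p = 0.5,
                                              alternative = "two.sided")$p.value
                          }),
      adjustment = "none"
    )
}

#' Fit an exponential age-vs-temperature curve
#'
#' Fits \eqn{age = A e^{-kT} + c} (days) by nonlinear least squares to the
#' per-temperature mean age for one life-history trait. With `k > 0` the
#' development time shortens towards the asymptote `c` as temperature
#' rises; this emergence-trait fit, shifted by the pre-oviposition period,
#' is the generation-time model used for voltinism mapping.
#'
#' @param records Individual records with `temperature_C`, `survived` and
#'   the age column for `trait`.
#' @param trait One of `"pupation"`, `"emergence"`, `"adult_death"`;
#'   selects column `age_<trait>_days`.
#' @param sex Optional: restrict to `"female"` or `"male"` survivors.
#' @return An `age_fit` object: `trait`, `coefficients` (A, k, c), `aic`,
#'   `degenerate` flag, and the per-temperature `means` used.
#' @export
fit_age_curve <- function(records, trait = c("emergence", "pupation", "adult_death"),
                          sex = NULL) {
  trait <- match.arg(trait)
  col <- paste0("age_", trait, "_days")
  check_columns(records, c("temperature_C", "survived", col))
  dat <- dplyr::filter(records, as.logical(.data$survived), !is.na(.data[[col]]))
  if (!is.null(sex)) dat <- dplyr::filter(dat, .data$sex == !!sex)
  means <- dat |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(mean_age = mean(.data[[col]]), n = dplyr::n(),
                     .groups = "drop")
  if (nrow(means) < 4) {
    stop("fit_age_curve needs mean ages at >= 4 temperatures with survivors")
  }
  x <- means$temperature_C
  y <- means$mean_age
  degenerate <- stats::sd(y) < 1e-8 * max(1, mean(y))
  if (degenerate) {
    warning("ages constant across temperatures: decay rate unidentifiable")
    cf <- c(A = 0, k = 0, c = mean(y))
    return(new_age_fit(trait, cf, NA_real_, TRUE, means))
  }
  start <- list(A = max(diff(range(y)), 1), k = 0.1, c = max(min(y) - 1, 0.1))
  fit <- minpack.lm::nlsLM(y ~ A * exp(-k * x) + c,
                           data = data.frame(x = x, y = y), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  new_age_fit(trait, cf, ls_aic(rss, length(y), 3), FALSE, means)
}

new_age_fit <- function(trait, coefficients, aic, degenerate, means) {
  structure(list(trait = trait, coefficients = coefficients, aic = aic,
                 degenerate = degenerate, means = means),
            class = "age_fit")
}

#' @export
print.age_fit <- function(x, ...) {
  cat("Exponential age-temperature fit, trait:", x$trait, "\n")
  cat(sprintf("  age = %.3f * exp(-%.4f T) + %.3f days\n",
              x$coefficients[["A"]], x$coefficients[["k"]], x$coefficients[["c"]]))
  invisible(x)
}

#' @export
predict.age_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$means$temperature_C else newdata$temperature_C
  cf <- object$coefficients
  cf[["A"]] * exp(-cf[["k"]] * t) + cf[["c"]]
}

#' Adult body-size summary
#'
#' Mean and SD of R1 wing-vein length (mm), the standard body-size proxy,
#' per temperature and sex.
#'
#' @param records Individual records with `temperature_C`, `sex`, `r1_mm`.
#' @return A tibble: `temperature_C`, `sex`, `n`, `mean_R1_mm`, `sd_mm`.
#' @export
size_summary <- function(records) {
  check_columns(records, c("temperature_C", "sex", "r1_mm"))
  records |>
    dplyr::filter(!is.na(.data$r1_mm), .data$sex %in% c("female", "male")) |>
    dplyr::group_by(.data$temperature_C, .data$sex) |>
    dplyr::summarise(n = dplyr::n(), mean_R1_mm = mean(.data$r1_mm),
                     sd_mm = stats::sd(.data$r1_mm), .groups = "drop")
}

#' Two-way ANOVA of body size on temperature and sex
#'
#' Fits `r1 ~ temperature * sex` (both as factors) on either the raw R1
#' wing-vein length or on the percent difference to the maximal observed
#' length, which removes the overall sexual size dimorphism so that a
#' remaining sex effect indicates sex-specific temperature response.
#'
#' @inheritParams size_summary
#' @param response `"length"` (raw mm, default) or `"pct_diff_max"`
#'   (percent difference to the maximum length within sex).
#' @return A tibble with one row per model term: `term`, `statistic`,
#'   `value`, `df1`, `df2`, `p`, `adjustment`.
#' @export
size_anova <- function(records, response = c("length", "pct_diff_max")) {
  response <- match.arg(response)
  check_columns(records, c("temperature_C", "sex", "r1_mm"))
  dat <- records |>
    dplyr::filter(!is.na(.data$r1_mm), .data$sex %in% c("female", "male"))
  if (length(unique(dat$temperature_C)) < 2 || length(unique(dat$sex)) < 2) {
    stop("size_anova needs >= 2 temperature levels and both sexes")
  }
  if (response == "pct_diff_max") {
    # reference is the maximal per-temperature mean length within each sex
    # (the single largest observation would be a noisy reference)
    dat <- dat |>
      dplyr::group_by(.data$sex, .data$temperature_C) |>
      dplyr::mutate(cell_mean = mean(.data$r1_mm)) |>
      dplyr::group_by(.data$sex) |>
      dplyr::mutate(y = 100 * (max(.data$cell_mean) - .data$r1_mm) /
                      max(.data$cell_mean)) |>
      dplyr::ungroup()
  } else {
    dat$y <- dat$r1_mm
  }
  fit <- stats::aov(y ~ factor(temperature_C) * factor(sex), data = dat)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  tibble::tibble(
    term = c("temperature", "sex", "temperature:sex")[seq_len(sum(keep))],
    statistic = "F",
    value = s$`F value`[keep],
    df1 = s$Df[keep],
    df2 = s$Df[!keep][1],
    p = s$`Pr(>F)`[keep],
    adjustment = "none"
  )
}
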