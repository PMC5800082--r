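#' Mean hatch success per temperature and exposure duration
#'
#' Averages per-cup hatch percentages (not pooled counts) within each
#' (temperature, exposure duration) cell, the convention used when several
#' replicate cups of eggs are flooded after a cold exposure.
#'
#' @param records A data frame of egg exposure records with columns
#'   `temperature_C`, `exposure_days`, `cup_id`, `n_eggs`, `n_hatched`.
#' @return A tibble with columns `temperature_C`, `exposure_days`, `n_cups`,
#'   `mean_hatch_pct`, `sd_hatch_pct`, sorted by temperature then duration.
#' @examples
#' rec <- tibble::tibble(temperature_C = 0, exposure_days = 0,
#'                       cup_id = 1:5, n_eggs = 20, n_hatched = c(20, 20, 20, 20, 20))
#' mean_hatch_success(rec)
#' @export
mean_hatch_success <- function(records) {
  check_columns(records, c("temperature_C", "exposure_days", "n_eggs", "n_hatched"))
  stopifnot(all(records$n_hatched >= 0), all(records$n_hatched <= records$n_eggs),
            all(records$exposure_days >= 0))
  records |>
    dplyr::mutate(hatch_pct = 100 * .data$n_hatched / .data$n_eggs) |>
    dplyr::group_by(.data$temperature_C, .data$exposure_days) |>
    dplyr::summarise(
      n_cups = dplyr::n(),
      mean_hatch_pct = mean(.data$hatch_pct),
      sd_hatch_pct = stats::sd(.data$hatch_pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$temperature_C, .data$exposure_days)
}

# hatch-curve families: percent scale, x in days
hatch_exponential <- function(x, A, k, c) A * exp(-k * x) + c
hatch_logistic <- function(x, L, B, r) L / (1 + B * exp(r * x))

# AIC for a least-squares fit: n log(RSS/n) + 2k, k = n_par + 1 for the
# residual variance, the usual NLS convention
ls_aic <- function(rss, n, n_par) n * log(rss / n) + 2 * (n_par + 1)

fit_one_family <- function(x, y, family) {
  if (family == "exponential") {
    dat <- data.frame(x = x, y = y)
    start <- list(A = max(diff(range(y)), 1e-3), k = 1 / max(stats::median(x), 0.25),
                  c = min(y))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-k * x) + c, data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    return(list(family = family, coefficients = cf, rss = rss,
                aic = ls_aic(rss, length(y), length(cf))))
  }
  fit_logistic_family(x, y)
}

# Logistic y = L / (1 + B e^{rx}) fitted in the well-conditioned
# reparameterisation y = D / (e^{rx} + s) with D = L/B, s = 1/B; when the
# curve is far from saturation B is enormous and only D and r are sharply
# identified, so optimising (L, B) directly stalls. Multi-start on (D, r, s).
fit_logistic_family <- function(x, y) {
  starts <- list()
  # log-linear guess for the decay tail
  pos <- y > max(y) * 1e-6 & y > 0
  if (sum(pos) >= 2) {
    ll <- stats::lm(log(y[pos]) ~ x[pos])
    r0 <- max(-unname(stats::coef(ll)[2]), 1e-3)
    D0 <- exp(unname(stats::coef(ll)[1]))
    starts <- c(starts, list(c(D = D0, r = r0, s = 1e-6),
                             c(D = D0, r = r0, s = 1)))
  }
  # scale-free default: L = 1.05 max(y), B solved from the first point, r = 1
  L0 <- max(y) * 1.05
  i1 <- which.min(x)
  y1 <- max(min(y[i1], L0 * 0.999), 1e-6)
  B0 <- max((L0 - y1) / y1, 1e-6) * exp(-x[i1])
  starts <- c(starts, list(c(D = L0 / B0, r = 1, s = 1 / B0)))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(p) y - p[["D"]] / (exp(p[["r"]] * x) + p[["s"]]),
        lower = c(D = 0, r = -10, s = 0),
        control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
  }
  if (is.null(best)) return(NULL)
  s <- max(best$par[["s"]], 1e-12)
  cf <- c(L = best$par[["D"]] / s, B = 1 / s, r = best$par[["r"]])
  list(family = "logistic", coefficients = cf, rss = best$rss,
       aic = ls_aic(best$rss, length(y), 3))
}

#' Fit an exposure-duration hatch curve
#'
#' Fits both an exponential decay \eqn{y = A e^{-kx} + c} and a logistic
#' decline \eqn{y = L / (1 + B e^{rx})} to mean hatch success (percent)
#' against exposure duration (days) by nonlinear least squares on the
#' percent scale, and returns the family with the lower AIC
#' (ties broken toward the exponential). The exponential asymptote `c` is
#' the minimal hatch success as exposure grows; for the logistic with a
#' positive rate the asymptote is 0.
#'
#' @param series A data frame with columns `exposure_days` and
#'   `mean_hatch_pct` (one row per duration), e.g. from
#'   [mean_hatch_success()], or a tibble of raw records which will be
#'   averaged first.
#' @param family `"auto"` (AIC selection, default), or force
#'   `"exponential"` / `"logistic"`.
#' @param transform Residual scale for fitting and AIC: `"percent"`
#'   (default) or `"arcsine"` (arcsin sqrt of the proportion).
#' @return A `hatch_fit` object: list with `family`, `coefficients`, `aic`,
#'   `aic_both` (named vector, both families), `minimal_hatch_pct`,
#'   `degenerate` (TRUE when the decay rate is unidentifiable, e.g. a
#'   constant series), and the fitted `data`.
#' @seealso [minimal_hatch()], [mean_hatch_success()]
#' @export
fit_hatch_curve <- function(series, family = c("auto", "exponential", "logistic"),
                            transform = c("percent", "arcsine")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (all(c("n_eggs", "n_hatched") %in% names(series))) {
    series <- mean_hatch_success(series) # raw records
  }
  check_columns(series, c("exposure_days", "mean_hatch_pct"))
  x <- series$exposure_days
  y <- series$mean_hatch_pct
  stopifnot(all(y >= 0 & y <= 100))
  if (length(unique(x)) < 4) {
    stop("need at least 4 distinct exposure durations to fit a hatch curve")
  }
  yfit <- if (transform == "arcsine") 100 * asin_sqrt(y / 100) else y

  degenerate <- stats::sd(y) < sqrt(.Machine$double.eps) * max(1, mean(y))
  if (degenerate) {
    cf <- c(A = 0, k = 0, c = mean(y))
    out <- new_hatch_fit("exponential", cf, aic = NA_real_,
                         aic_both = c(exponential = NA_real_, logistic = NA_real_),
                         minimal_hatch_pct = mean(y), degenerate = TRUE,
                         data = series, transform = transform)
    warning("constant hatch series: decay rate unidentifiable, asymptote set to the mean")
    return(out)
  }

  fits <- list()
  if (family %in% c("auto", "exponential")) fits$exponential <- fit_one_family(x, yfit, "exponential")
  if (family %in% c("auto", "logistic")) fits$logistic <- fit_one_family(x, yfit, "logistic")
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("both hatch-curve families failed to converge")
  if (family == "auto" && length(fits) == 1) {
    warning(sprintf("only the %s family converged", names(fits)[1]))
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  # ties (within numerical noise) go to the exponential family
  best <- if ("exponential" %in% names(fits) &&
              aics[["exponential"]] <= min(aics) + 1e-9) "exponential" else names(which.min(aics))
  f <- fits[[best]]
  cf <- f$coefficients
  asym_raw <- if (best == "exponential") {
    cf[["c"]]
  } else if (cf[["r"]] > 0) 0 else if (cf[["r"]] < 0) cf[["L"]] else {
    cf[["L"]] / (1 + cf[["B"]])
  }
  minimal <- if (transform == "arcsine") {
    # asymptote back-transformed to percent for reporting
    100 * sin(min(max(asym_raw / 100, 0), pi / 2))^2
  } else asym_raw
  minimal <- min(max(minimal, 0), 100)
  aic_both <- c(exponential = NA_real_, logistic = NA_real_)
  aic_both[names(aics)] <- aics
  new_hatch_fit(best, cf, aic = f$aic, aic_both = aic_both,
                minimal_hatch_pct = minimal, degenerate = FALSE,
                data = series, transform = transform)
}

new_hatch_fit <- function(family, coefficients, aic, aic_both,
                          minimal_hatch_pct, degenerate, data, transform) {
  structure(
    list(family = family, coefficients = coefficients, aic = aic,
         aic_both = aic_both, minimal_hatch_pct = minimal_hatch_pct,
         degenerate = degenerate, data = data, transform = transform),
    class = "hatch_fit"
  )
}

#' @export
print.hatch_fit <- function(x, ...) {
  cat("Hatch-vs-exposure curve fit (", x$family, " family)\n", sep = "")
  print(round(x$coefficients, 4))
  cat("AIC:", format(x$aic, digits = 5),
      " minimal hatch:", format(x$minimal_hatch_pct, digits = 4), "%\n")
  invisible(x)
}

#' Predict hatch success from a fitted curve
#'
#' @param object A `hatch_fit`.
#' @param newdata Optional data frame with an `exposure_days` column;
#'   defaults to the fitted durations.
#' @param ... Unused.
#' @return Numeric vector of hatch percentages.
#' @export
predict.hatch_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$exposure_days else newdata$exposure_days
  cf <- object$coefficients
  y <- if (object$family == "exponential") {
    hatch_exponential(x, cf[["A"]], cf[["k"]], cf[["c"]])
  } else {
    hatch_logistic(x, cf[["L"]], cf[["B"]], cf[["r"]])
  }
  if (object$transform == "arcsine") 100 * sin(pmin(pmax(y / 100, 0), pi / 2))^2 else y
}

#' Asymptotic minimal hatch success, truncated to whole percent
#'
#' The asymptote of the fitted curve as exposure duration grows without
#' bound — the exponential offset `c`, or 0 for a decreasing logistic —
#' truncated (not rounded) to an integer percentage.
#'
#' @param fit A `hatch_fit` object.
#' @return Integer percent in `[0, 100]`.
#' @examples
#' \dontrun{minimal_hatch(fit)  # e.g. 36 for an asymptote of 36.12}
#' @export
minimal_hatch <- function(fit) {
  stopifnot(inherits(fit, "hatch_fit"))
  as.integer(trunc(fit$minimal_hatch_pct))
}

#' Test for an effect of exposure length on hatch success
#'
#' One-way regression F-test of the arcsine-square-root-transformed hatch
#' proportion on exposure duration, computed on per-duration mean hatch
#' success (so with d durations the F statistic has (1, d - 2) degrees of
#' freedom).
#'
#' @param records Egg exposure records for a single temperature (columns
#'   `exposure_days`, `n_eggs`, `n_hatched`; a `temperature_C` column, if
#'   present, must be constant).
#' @return A one-row tibble: `statistic` ("F"), `value`, `df1`, `df2`, `p`,
#'   `adjustment` ("none").
#' @export
exposure_effect_test <- function(records) {
  if ("temperature_C" %in% names(records) &&
      length(unique(records$temperature_C)) > 1) {
    stop("exposure_effect_test expects records from a single temperature")
  }
  ms <- mean_hatch_success(dplyr::mutate(records, temperature_C = 1))
  dat <- data.frame(x = ms$exposure_days,
                    y = asin_sqrt(ms$mean_hatch_pct / 100))
  if (stats::sd(dat$y) == 0) {
    # no variation at all: no exposure effect by definition
    return(tibble::tibble(statistic = "F", value = 0,
                          df1 = 1, df2 = nrow(dat) - 2, p = 1,
                          adjustment = "none"))
  }
  fit <- stats::lm(y ~ x, data = dat)
  an <- stats::anova(fit)
  tibble::tibble(statistic = "F", value = an$`F value`[1],
                 df1 = an$Df[1], df2 = an$Df[2],
                 p = an$`Pr(>F)`[1], adjustment = "none")
}
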