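#' Build thermal performance points from life-history records
#'
#' Thermal performance is cumulative female survival: the proportion of
#' larvae surviving to adulthood multiplied by the female developmental
#' rate (the inverse of the mean female age at emergence, day^-1).
#' Temperatures with no emerged females get performance 0.
#'
#' @param records Individual life-history records with `temperature_C`,
#'   `survived`, `sex`, `age_emergence_days`.
#' @return A tibble of TPC points: `temperature_C`, `survival` (0-1),
#'   `dev_rate_per_day` (0 when no female emerged), `performance`
#'   (day^-1).
#' @export
build_tpc_points <- function(records) {
  check_columns(records, c("temperature_C", "survived", "sex", "age_emergence_days"))
  surv <- records |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(survival = mean(as.numeric(.data$survived)), .groups = "drop")
  dev <- records |>
    dplyr::filter(as.logical(.data$survived), .data$sex == "female",
                  !is.na(.data$age_emergence_days)) |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(dev_rate_per_day = 1 / mean(.data$age_emergence_days),
                     .groups = "drop")
  surv |>
    dplyr::left_join(dev, by = "temperature_C") |>
    dplyr::mutate(
      dev_rate_per_day = dplyr::coalesce(.data$dev_rate_per_day, 0),
      performance = .data$survival * .data$dev_rate_per_day
    ) |>
    dplyr::arrange(.data$temperature_C)
}

# ---- candidate models for the zoo -----------------------------------------

# each candidate: name, n_par, predict(par, T), multi-start list builder
zoo_candidates <- function(points) {
  t <- points$temperature_C
  y <- points$performance
  pos <- t[y > 0]
  tmin0 <- if (length(pos)) min(pos) - 2 else min(t)
  tmax0 <- if (length(pos)) max(pos) + 2 else max(t)
  peak <- max(y)
  tpk <- t[which.max(y)]
  a0 <- function(m) {
    denom <- tpk * max(tpk - tmin0, 1) * max(tmax0 - tpk, 1)^(1 / m)
    max(peak / max(denom, 1e-12), 1e-12)
  }
  list(
    briere1 = list(
      n_par = 4,
      fn = function(p, T) briere1(T, p[["a"]], p[["m"]], p[["t_min"]], p[["t_max"]]),
      starts = lapply(c(1, 2, 4), function(m) {
        c(a = a0(m), m = m, t_min = tmin0, t_max = tmax0)
      }),
      lower = c(a = 1e-12, m = 0.1, t_min = -50, t_max = max(t) - 1),
      upper = c(a = 1, m = 50, t_min = min(t) + 15, t_max = 60)
    ),
    briere1_m2 = list(
      n_par = 3,
      fn = function(p, T) briere1(T, p[["a"]], 2, p[["t_min"]], p[["t_max"]]),
      starts = list(c(a = a0(2), t_min = tmin0, t_max = tmax0)),
      lower = c(a = 1e-12, t_min = -50, t_max = max(t) - 1),
      upper = c(a = 1, t_min = min(t) + 15, t_max = 60)
    ),
    quadratic = list(
      n_par = 3,
      fn = function(p, T) pmax(p[["b0"]] + p[["b1"]] * T + p[["b2"]] * T^2, 0),
      starts = list({
        b2 <- -peak / max((tmax0 - tmin0) / 2, 1)^2
        c(b0 = peak + b2 * tpk^2 - 2 * b2 * tpk * tpk, b1 = -2 * b2 * tpk, b2 = b2)
      }),
      lower = c(b0 = -Inf, b1 = -Inf, b2 = -Inf),
      upper = c(b0 = Inf, b1 = Inf, b2 = 0)
    ),
    gaussian = list(
      n_par = 3,
      fn = function(p, T) p[["ymax"]] * exp(-0.5 * ((T - p[["t_opt"]]) / p[["sd"]])^2),
      starts = list(c(ymax = peak, t_opt = tpk, sd = (tmax0 - tmin0) / 4)),
      lower = c(ymax = 0, t_opt = -50, sd = 0.1),
      upper = c(ymax = Inf, t_opt = 60, sd = 100)
    ),
    linear_threshold = list(
      n_par = 2,
      fn = function(p, T) pmax(p[["slope"]] * (T - p[["t_min"]]), 0),
      starts = list(c(slope = peak / max(tpk - tmin0, 1), t_min = tmin0)),
      lower = c(slope = 0, t_min = -50),
      upper = c(slope = Inf, t_min = min(t) + 15)
    )
  )
}

fit_candidate <- function(cand, t, y) {
  best <- NULL
  for (start in cand$starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(p) y - cand$fn(p, t),
        lower = cand$lower[names(start)], upper = cand$upper[names(start)],
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
  }
  best
}

#' Fit a zoo of thermal performance models and compare by AIC weight
#'
#' Fits each candidate model (Briere-1 with free shape, Briere-1 with the
#' shape fixed at m = 2, a truncated quadratic, a Gaussian, and a linear
#' model with a lower threshold) by nonlinear least squares with
#' multi-start initialisation, and ranks them by AIC converted to Akaike
#' weights. Candidates that fail to converge are reported with infinite
#' AIC and zero weight rather than aborting the selection.
#'
#' @param points TPC points from [build_tpc_points()] (or any data frame
#'   with `temperature_C` and `performance`).
#' @param models Character vector naming a subset of the candidate zoo;
#'   default all.
#' @return A `tpc_zoo` object: `report` tibble (model, n_par, rss, aic,
#'   aic_weight, estimates as a list-column), `best` (name of the winning
#'   model), and `briere` (a `briere_fit` for the best Briere-form
#'   candidate, with cardinal temperatures).
#' @export
fit_model_zoo <- function(points, models = NULL) {
  check_columns(points, c("temperature_C", "performance"))
  t <- points$temperature_C
  y <- points$performance
  if (length(t) < 5) stop("fit_model_zoo needs at least 5 temperature points")
  if (all(y <= 0)) stop("all performance values are zero: nothing to fit")
  cands <- zoo_candidates(points)
  if (!is.null(models)) cands <- cands[intersect(models, names(cands))]
  n <- length(y)
  rows <- purrr::imap_dfr(cands, function(cand, nm) {
    f <- fit_candidate(cand, t, y)
    if (is.null(f)) {
      tibble::tibble(model = nm, n_par = cand$n_par, rss = Inf, aic = Inf,
                     estimates = list(NULL))
    } else {
      tibble::tibble(model = nm, n_par = cand$n_par, rss = f$rss,
                     aic = ls_aic(f$rss, n, cand$n_par),
                     estimates = list(f$par))
    }
  })
  d <- rows$aic - min(rows$aic)
  w <- exp(-0.5 * d)
  w[!is.finite(w)] <- 0
  rows$aic_weight <- w / sum(w)
  rows <- dplyr::arrange(rows, .data$aic)
  best <- rows$model[1]
  briere_row <- rows[rows$model %in% c("briere1", "briere1_m2"), ][1, ]
  bf <- NULL
  if (is.finite(briere_row$aic)) {
    p <- briere_row$estimates[[1]]
    m <- if (briere_row$model == "briere1_m2") 2 else p[["m"]]
    bf <- new_briere_fit(a = p[["a"]], m = m,
                         t_min = p[["t_min"]], t_max = p[["t_max"]],
                         aic = briere_row$aic, aic_weight = briere_row$aic_weight,
                         points = points)
  }
  structure(list(report = rows, best = best, briere = bf), class = "tpc_zoo")
}

#' @export
print.tpc_zoo <- function(x, ...) {
  cat("Thermal performance model selection (", nrow(x$report), " candidates)\n",
      sep = "")
  print(dplyr::select(x$report, "model", "n_par", "aic", "aic_weight"))
  cat("best model:", x$best, "\n")
  invisible(x)
}

#' Fit the Briere-1 model to thermal performance points
#'
#' Nonlinear least-squares fit of
#' \eqn{y = aT(T - T_{min})(T_{max} - T)^{1/m}} with multi-start
#' initialisation (lower limit from the coldest temperature with positive
#' performance minus 2 degrees, upper from the warmest plus 2, scale from
#' the peak). The optimum temperature is derived from the fitted limits by
#' root-finding on the analytic derivative.
#'
#' @inheritParams fit_model_zoo
#' @param fix_m Optional: fix the shape constant (e.g. `fix_m = 2`).
#' @return A `briere_fit`: `a`, `m`, `t_min`, `t_max`, `t_opt`, `aic`,
#'   and the fitted `points`.
#' @export
fit_briere1 <- function(points, fix_m = NULL) {
  check_columns(points, c("temperature_C", "performance"))
  which_model <- if (is.null(fix_m)) "briere1" else "briere1_m2"
  cands <- zoo_candidates(points)
  cand <- cands[[which_model]]
  f <- fit_candidate(cand, points$temperature_C, points$performance)
  if (is.null(f)) stop("Briere-1 fit failed to converge")
  p <- f$par
  m <- if (is.null(fix_m)) p[["m"]] else fix_m
  new_briere_fit(a = p[["a"]], m = m, t_min = p[["t_min"]], t_max = p[["t_max"]],
                 aic = ls_aic(f$rss, nrow(points), cand$n_par),
                 aic_weight = NA_real_, points = points)
}

new_briere_fit <- function(a, m, t_min, t_max, aic, aic_weight, points) {
  structure(
    list(a = a, m = m, t_min = t_min, t_max = t_max,
         t_opt = briere1_topt(m = m, t_min = t_min, t_max = t_max, a = a),
         aic = aic, aic_weight = aic_weight, points = points),
    class = "briere_fit"
  )
}

#' @export
print.briere_fit <- function(x, ...) {
  cat("Briere-1 thermal performance fit\n")
  cat(sprintf("  a = %.3g, m = %.3f\n", x$a, x$m))
  cat(sprintf("  T_min = %.2f, T_opt = %.2f, T_max = %.2f degrees C\n",
              x$t_min, x$t_opt, x$t_max))
  invisible(x)
}

#' @export
predict.briere_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$points$temperature_C else newdata$temperature_C
  briere1(t, object$a, object$m, object$t_min, object$t_max)
}
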