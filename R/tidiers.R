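#' Tidy a hatch-curve fit
#'
#' @param x A `hatch_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.hatch_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.hatch_fit
#' @export
glance.hatch_fit <- function(x, ...) {
  tibble::tibble(family = x$family, aic = x$aic,
                 minimal_hatch_pct = x$minimal_hatch_pct,
                 degenerate = x$degenerate, n = nrow(x$data))
}

#' Tidy a Briere-1 thermal performance fit
#'
#' @param x A `briere_fit`.
#' @param ... Unused.
#' @return One row per parameter (`a`, `m`, `t_min`, `t_max`, and the
#'   derived `t_opt`).
#' @export
tidy.briere_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "m", "t_min", "t_max", "t_opt"),
    estimate = c(x$a, x$m, x$t_min, x$t_max, x$t_opt),
    derived = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' @rdname tidy.briere_fit
#' @export
glance.briere_fit <- function(x, ...) {
  tibble::tibble(aic = x$aic, aic_weight = x$aic_weight,
                 t_opt = x$t_opt, n = nrow(x$points))
}

#' Tidy an age-vs-temperature fit
#'
#' @param x An `age_fit`.
#' @param ... Unused.
#' @return One row per coefficient.
#' @export
tidy.age_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.age_fit
#' @export
glance.age_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, aic = x$aic, degenerate = x$degenerate,
                 n_temperatures = nrow(x$means))
}

#' Tidy a thermal-performance model selection report
#'
#' @param x A `tpc_zoo`.
#' @param ... Unused.
#' @return The selection table (model, n_par, rss, aic, aic_weight).
#' @export
tidy.tpc_zoo <- function(x, ...) {
  dplyr::select(x$report, -"estimates")
}
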