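#' Briere-1 thermal performance function
#'
#' Evaluates the asymmetric thermal performance curve
#' \deqn{y = a\,T\,(T - T_{min})\,(T_{max} - T)^{1/m}}
#' which is zero at both cardinal limits and peaked between them. Outside
#' \eqn{[T_{min}, T_{max}]} the curve is defined as 0, so the function is
#' continuous and non-negative everywhere.
#'
#' @param temp_C Numeric vector of temperatures (degrees C).
#' @param a Empirical scale constant (day^-1 scale; multiplies the curve).
#' @param m Empirical shape constant (> 0); `m = 2` gives the square-root
#'   fall-off used for cumulative female survival.
#' @param t_min,t_max Lower and upper thermal limits (degrees C),
#'   `t_min < t_max`.
#' @return Numeric vector of performance values (same units as `a` implies,
#'   typically day^-1), zero outside `[t_min, t_max]`.
#' @examples
#' briere1(26, a = 6e-6, m = 2, t_min = 7, t_max = 31)
#' @export
briere1 <- function(temp_C, a, m, t_min, t_max) {
  stopifnot(is.numeric(temp_C), a > 0, m > 0, t_min < t_max)
  y <- a * temp_C * (temp_C - t_min) * (pmax(t_max - temp_C, 0))^(1 / m)
  y[temp_C < t_min | temp_C > t_max] <- 0
  y[!is.finite(temp_C)] <- NA_real_
  y
}

# analytic derivative of briere1 on the open interval (t_min, t_max)
briere1_deriv <- function(temp_C, a, m, t_min, t_max) {
  u <- t_max - temp_C
  a * ((2 * temp_C - t_min) * u^(1 / m) -
         (1 / m) * temp_C * (temp_C - t_min) * u^(1 / m - 1))
}

#' Optimum temperature of a Briere-1 curve
#'
#' Finds the temperature maximising the Briere-1 curve as the unique root of
#' the first derivative dy/dT = 0 on the open interval
#' (`t_min`, `t_max`), by bracketed root-finding on the analytic derivative.
#' The root coincides with the closed-form quadratic solution
#' \deqn{T_{opt} = \frac{2 m T_{max} + (m+1) T_{min} +
#'   \sqrt{4 m^2 T_{max}^2 + (m+1)^2 T_{min}^2 - 4 m^2 T_{min} T_{max}}}
#'   {4 m + 2}}
#' (the larger root lies in the interval); the numeric route is used so that
#' the result is defined for any differentiable reparameterisation.
#'
#' @inheritParams briere1
#' @param tol Convergence tolerance passed to [stats::uniroot()], in degrees C.
#' @return Optimum temperature in degrees C.
#' @examples
#' briere1_topt(m = 2, t_min = 7, t_max = 31)  # ~25.6, rounds to 26
#' @export
briere1_topt <- function(m, t_min, t_max, a = 1, tol = 1e-9) {
  stopifnot(m > 0, t_min < t_max)
  eps <- (t_max - t_min) * 1e-9
  root <- stats::uniroot(
    briere1_deriv,
    interval = c(t_min + eps, t_max - eps),
    a = a, m = m, t_min = t_min, t_max = t_max,
    tol = tol
  )$root
  root
}

#' Cardinal temperatures of a fitted Briere-1 model
#'
#' @param fit A `briere_fit` object from [fit_briere1()] or the Briere entry
#'   of [fit_model_zoo()].
#' @return A tibble with one row: `t_min`, `t_opt`, `t_max` (degrees C).
#' @export
cardinal_temperatures <- function(fit) {
  stopifnot(inherits(fit, "briere_fit"))
  tibble::tibble(t_min = fit$t_min, t_opt = fit$t_opt, t_max = fit$t_max)
}
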