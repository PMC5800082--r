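#' @importFrom rlang .data
#' @importFrom generics tidy glance augment
NULL

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Arcsine square-root transform of a proportion
#'
#' `asin(sqrt(p))` for `p` in `[0, 1]` — the classical variance-stabilising
#' transform for binomial proportions, used before the ANOVA and
#' regression tests on mortality and hatch fractions.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]` radians.
#' @export
asin_sqrt <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  asin(sqrt(p))
}

#' @export
generics::tidy

#' @export
generics::glance
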