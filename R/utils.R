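# internal helpers shared across modules

# round half away from zero (reports mirror the printed tables, which use
# conventional half-up rounding rather than IEEE round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # sqrt(eps) guard keeps decimal halves (e.g. 2.41475 stored as
  # 2.4147499999...) on the half-up side of the boundary
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# log10-spaced dose grid
#' Dose grids
#'
#' Build a dose grid between `min` and `max`, log-spaced by default (the
#' natural spacing for median-effect experiments, whose analysis is linear
#' in log dose).
#'
#' @param min,max Dose range, mg/mL; both must be positive for a log grid.
#' @param n Number of doses.
#' @param log Logical; log10-spacing (default) or arithmetic.
#' @return Numeric vector of `n` doses, increasing.
#' @examples
#' dose_grid(0.005, 1, 10)
#' @export
dose_grid <- function(min, max, n, log = TRUE) {
  stopifnot(n >= 2, max > min)
  if (log) {
    if (min <= 0) abort("log-spaced dose grid requires min > 0")
    10^seq(log10(min), log10(max), length.out = n)
  } else {
    seq(min, max, length.out = n)
  }
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) abort(sprintf("`%s` must be finite", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0 (got %g)", name, x))
  invisible(x)
}

check_fraction <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) abort(sprintf("`%s` must be numeric", name))
  bad <- if (open) x <= 0 | x >= 1 else x < 0 | x > 1
  if (any(bad)) {
    abort(sprintf(
      "`%s` must lie %s (offending value: %g)",
      name, if (open) "strictly in (0, 1)" else "in [0, 1]", x[bad][1]
    ))
  }
  invisible(x)
}

require_columns <- function(data, cols, caller) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: input is missing required column(s): %s",
      caller, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
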