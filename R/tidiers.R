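#' Tidy a median-effect fit
#'
#' One row per model quantity, broom-style: the sigmoidicity coefficient
#' `m` (with its OLS standard error), the median-effect plot intercept, and
#' the derived median-effect dose `Dm`.
#'
#' @param x An [me_fit] object.
#' @param ... Unused.
#' @return A tibble with columns `agent_id`, `term`, `estimate`,
#'   `std.error`.
#' @exportS3Method generics::tidy
tidy.me_fit <- function(x, ...) {
  tibble::tibble(
    agent_id = x$agent_id,
    term = c("m", "intercept", "Dm"),
    estimate = c(x$m, x$intercept, x$dm),
    std.error = c(x$m_se, NA_real_, NA_real_)
  )
}

#' One-row summary of a median-effect fit
#'
#' @param x An [me_fit] object.
#' @param ... Unused.
#' @return A one-row tibble: `agent_id`, `dm`, `m`, `m_se`, `r`, `r_ok`
#'   (the r >= 0.95 acceptability flag), `n_used`, `n_excluded`.
#' @exportS3Method generics::glance
glance.me_fit <- function(x, ...) {
  tibble::tibble(
    agent_id = x$agent_id,
    dm = x$dm, m = x$m, m_se = x$m_se,
    r = x$r, r_ok = x$r_ok,
    n_used = x$n_used, n_excluded = nrow(x$excluded)
  )
}

#' @rdname glance.me_fit
#' @exportS3Method generics::glance
glance.combo_fit <- function(x, ...) {
  out <- NextMethod()
  out$ratio <- x$ratio
  out$d1 <- x$d1
  out$d2 <- x$d2
  out
}
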