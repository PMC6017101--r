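#' Fit the median-effect equation to dose-effect data
#'
#' Fits the median-effect (mass-action) model `fa/fu = (D/Dm)^m` by ordinary
#' least squares on its exact linearization, the median-effect plot:
#' `log10(fa/fu)` against `log10(D)`. The slope is the sigmoidicity
#' coefficient `m` (analogous to a Hill coefficient) and the median-effect
#' dose is recovered as `Dm = 10^(-intercept/m)` — the dose giving 50%
#' effect, i.e. the IC50 here. The signed Pearson correlation `r` of the
#' transformed points is reported as the conventional quality-control
#' statistic; fits with `r >= 0.95` are flagged acceptable, but the rule is
#' never enforced as a failure.
#'
#' Points with `fa` at or outside the usability band are excluded before
#' fitting because the log-odds transform diverges at 0 and 1; the excluded
#' points and reasons are kept on the returned object. Replicate points
#' enter the regression individually by default, preserving the error
#' structure; set `average_replicates = TRUE` to fit dose-wise means of the
#' transformed response instead.
#'
#' @param data A data frame of dose-effect points with columns `dose`
#'   (mg/mL, > 0) and `fraction_affected` (in \[0, 1\]); an `agent_id`
#'   column is honoured if present.
#' @param agent_id Which agent to fit when `data` holds several; required
#'   in that case, otherwise inferred.
#' @param band Usability band: points with `fa <= band[1]` or
#'   `fa >= band[2]` are excluded. Default `c(0.005, 0.995)`.
#' @param average_replicates Average transformed replicates per dose before
#'   the regression. Default `FALSE`.
#' @return An object of class `me_fit`: a list with elements `agent_id`,
#'   `dm`, `m`, `m_se`, `r`, `r_ok`, `n_used`, `excluded` (tibble of dropped
#'   points with reasons), `band`, and `points` (the transformed points
#'   used, columns `dose`, `fraction_affected`, `x`, `y`). Methods:
#'   [tidy()], [glance()], [autoplot()], `print`.
#' @examples
#' d <- tibble::tibble(dose = c(0.25, 0.5, 1, 2, 4))
#' d$fraction_affected <- d$dose / (1 + d$dose) # Dm = 1, m = 1
#' fit_median_effect(d)
#' @export
fit_median_effect <- function(data, agent_id = NULL, band = c(0.005, 0.995),
                              average_replicates = FALSE) {
  require_columns(data, c("dose", "fraction_affected"), "fit_median_effect")
  stopifnot(length(band) == 2, band[1] >= 0, band[2] <= 1, band[1] < band[2])

  if ("agent_id" %in% names(data)) {
    ids <- unique(data$agent_id)
    if (is.null(agent_id)) {
      if (length(ids) > 1L) {
        abort(sprintf(
          "data holds %d agents (%s); pass `agent_id` to pick one",
          length(ids), paste(ids, collapse = ", ")
        ))
      }
      agent_id <- ids
    } else {
      if (!agent_id %in% ids) abort(sprintf("agent '%s' not present in data", agent_id))
      data <- dplyr::filter(data, .data$agent_id == !!agent_id)
    }
  } else if (is.null(agent_id)) {
    agent_id <- "agent"
  }

  if (anyNA(data$dose) || anyNA(data$fraction_affected)) {
    abort("fit_median_effect: dose and fraction_affected must not contain NA")
  }
  if (any(data$dose <= 0)) abort("fit_median_effect: all doses must be strictly positive")
  check_fraction(data$fraction_affected, "fraction_affected", open = FALSE)

  usable <- data$fraction_affected > band[1] & data$fraction_affected < band[2]
  excluded <- tibble::tibble(
    dose = data$dose[!usable],
    fraction_affected = data$fraction_affected[!usable],
    reason = ifelse(
      data$fraction_affected[!usable] <= band[1],
      sprintf("fa <= %g (lower usability bound)", band[1]),
      sprintf("fa >= %g (upper usability bound)", band[2])
    )
  )
  pts <- tibble::tibble(
    dose = data$dose[usable],
    fraction_affected = data$fraction_affected[usable]
  )
  if (nrow(pts) < 2L || length(unique(pts$dose)) < 2L) {
    detail <- if (nrow(excluded) > 0) {
      paste0(
        "; excluded points: ",
        paste(sprintf("dose %g (%s)", excluded$dose, excluded$reason), collapse = "; ")
      )
    } else ""
    abort(sprintf(
      "fit_median_effect('%s'): need >= 2 usable points at >= 2 distinct doses, have %d at %d dose(s)%s",
      agent_id, nrow(pts), length(unique(pts$dose)), detail
    ))
  }

  pts$x <- log10(pts$dose)
  pts$y <- log10(pts$fraction_affected / (1 - pts$fraction_affected))
  if (average_replicates) {
    pts <- dplyr::summarise(
      dplyr::group_by(pts, .data$dose),
      fraction_affected = mean(.data$fraction_affected),
      x = .data$x[1], y = mean(.data$y), .groups = "drop"
    )
  }

  ls_fit <- lm(y ~ x, data = pts)
  m <- unname(coef(ls_fit)[2])
  b <- unname(coef(ls_fit)[1])
  # exact (noise-free) data triggers lm's "essentially perfect fit" warning;
  # the zero standard error it returns is the right answer there
  m_se <- suppressWarnings(summary(ls_fit)$coefficients[2, 2])
  dm <- 10^(-b / m)
  r <- stats::cor(pts$x, pts$y)

  structure(
    list(
      agent_id = agent_id, dm = dm, m = m, m_se = m_se,
      intercept = b, r = r, r_ok = !is.na(r) && r >= 0.95,
      n_used = nrow(pts), excluded = excluded, band = band, points = pts
    ),
    class = "me_fit"
  )
}

#' Construct a median-effect fit from known parameters
#'
#' Builds an `me_fit` object directly from `(Dm, m)`, for worked examples
#' and for computing CI/DRI from published parameter tables where the raw
#' dose-effect points are unavailable.
#'
#' @param dm Median-effect dose (mg/mL, > 0).
#' @param m Sigmoidicity coefficient (> 0).
#' @param agent_id Label.
#' @return An `me_fit` with `r`, `m_se`, `n_used` set to `NA`.
#' @examples
#' bromelain <- me_fit(dm = 0.0723, m = 0.6767, agent_id = "bromelain")
#' compute_dx(bromelain, 0.9)
#' @export
me_fit <- function(dm, m, agent_id = "agent") {
  check_number(dm, "dm", positive = TRUE)
  check_number(m, "m")
  structure(
    list(
      agent_id = agent_id, dm = dm, m = m, m_se = NA_real_,
      intercept = -m * log10(dm), r = NA_real_, r_ok = NA,
      n_used = NA_integer_, excluded = tibble::tibble(), band = NULL,
      points = NULL
    ),
    class = "me_fit"
  )
}

#' @export
print.me_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit: %s\n", x$agent_id))
  cat(sprintf("  Dm = %.4g mg/mL   m = %.4g", x$dm, x$m))
  if (!is.na(x$m_se)) cat(sprintf(" +/- %.4g", x$m_se))
  cat("\n")
  if (!is.na(x$r)) {
    cat(sprintf(
      "  r = %.4f (%s), %d point(s) used, %d excluded\n",
      x$r, if (isTRUE(x$r_ok)) "acceptable, r >= 0.95" else "below 0.95",
      x$n_used, nrow(x$excluded)
    ))
  }
  invisible(x)
}

check_me_fit <- function(fit, caller) {
  if (!inherits(fit, "me_fit")) abort(sprintf("%s: expected an `me_fit` object", caller))
  if (!is.finite(fit$m) || fit$m <= 0) {
    abort(sprintf(
      "%s: fit for '%s' has non-physical slope m = %g (must be > 0)",
      caller, fit$agent_id, fit$m
    ))
  }
  invisible(fit)
}

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa / (1 - fa))^(1/m)`,
#' the dose an agent needs alone to reach effect level `fa`. Strictly
#' increasing in `fa` for `m > 0`; `compute_dx(fit, 0.5)` is `Dm` exactly.
#'
#' @param fit An [me_fit] object.
#' @param fa Effect level(s), each strictly in (0, 1). Vectorized.
#' @return Dose(s) in mg/mL.
#' @export
compute_dx <- function(fit, fa) {
  check_me_fit(fit, "compute_dx")
  check_fraction(fa, "fa", open = TRUE)
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Effect level at a given dose
#'
#' Forward form of the median-effect equation:
#' `fa = 1 / (1 + (Dm/D)^m)`. Inverse of [compute_dx()]; the two compose to
#' the identity. Strictly increasing in dose for `m > 0`, with
#' `predict_fa(fit, Dm) == 0.5`.
#'
#' @param fit An [me_fit] object.
#' @param dose Dose(s) in mg/mL, each > 0. Vectorized.
#' @return Fraction(s) affected, in (0, 1).
#' @export
predict_fa <- function(fit, dose) {
  check_me_fit(fit, "predict_fa")
  if (!is.numeric(dose) || anyNA(dose) || any(dose <= 0)) {
    abort("predict_fa: dose must be numeric and > 0")
  }
  1 / (1 + (fit$dm / dose)^fit$m)
}
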