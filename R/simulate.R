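#' Simulate single-agent dose-effect data from the median-effect model
#'
#' Generates dose-effect points under the generative form of the
#' median-effect equation: for each dose and replicate,
#' `y = m * log10(D / Dm) + e` with `e ~ N(0, noise_sd^2)`, then
#' `fa = 10^y / (1 + 10^y)`. Noise lives on the transformed (log-odds)
#' scale — the scale on which the fit is linear — which keeps every
#' generated fraction strictly inside (0, 1). With `noise_sd = 0` the
#' points lie exactly on the median-effect curve, so generation composed
#' with [fit_median_effect()] is the identity on `(Dm, m)`.
#'
#' A clipped raw-scale Gaussian mode (`noise_on = "fa"`) is provided for
#' robustness testing; it adds noise directly to `fa` and clips to the
#' open unit interval, mimicking assay error that is additive in percent
#' inhibition.
#'
#' @param dm,m Generating truth: median-effect dose (mg/mL, > 0) and
#'   sigmoidicity coefficient (> 0).
#' @param doses Dose vector (mg/mL, > 0); default 10 log-spaced doses
#'   0.005-1 (see [dose_grid()]).
#' @param noise_sd Standard deviation of the Gaussian noise (transformed
#'   scale unless `noise_on = "fa"`); >= 0.
#' @param replicates Replicate points per dose; default 3.
#' @param seed Optional integer seed; the same spec and seed give an
#'   identical series, and the caller's RNG state is left untouched.
#' @param agent_id Label for the series.
#' @param noise_on `"transformed"` (default) or `"fa"`.
#' @return A tibble with columns `agent_id`, `replicate`, `dose`,
#'   `fraction_affected`.
#' @examples
#' simulate_single_agent(dm = 1, m = 1, doses = c(0.5, 1, 2), noise_sd = 0)
#' @export
simulate_single_agent <- function(dm, m, doses = dose_grid(0.005, 1, 10),
                                  noise_sd = 0, replicates = 3, seed = NULL,
                                  agent_id = "agent",
                                  noise_on = c("transformed", "fa")) {
  check_number(dm, "dm", positive = TRUE)
  check_number(m, "m", positive = TRUE)
  if (length(doses) == 0 || any(doses <= 0)) abort("doses must be positive and non-empty")
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  stopifnot(replicates >= 1)
  noise_on <- match.arg(noise_on)

  grid <- tidyr::expand_grid(replicate = seq_len(replicates), dose = as.numeric(doses))
  y <- m * log10(grid$dose / dm)
  fa <- with_seed_if(seed, {
    if (noise_on == "transformed") {
      yy <- y + stats::rnorm(nrow(grid), 0, noise_sd)
      10^yy / (1 + 10^yy)
    } else {
      pmin(pmax(10^y / (1 + 10^y) + stats::rnorm(nrow(grid), 0, noise_sd), 1e-9), 1 - 1e-9)
    }
  })
  tibble::tibble(
    agent_id = agent_id,
    replicate = grid$replicate,
    dose = grid$dose,
    fraction_affected = fa
  )
}

#' Simulate constant-ratio mixture data with a controlled true CI
#'
#' Generates dose-effect data for a fixed-ratio two-agent mixture whose
#' true combination index is imposed pointwise at every dose. For total
#' dose `D` the component doses are `d1 = ratio * D`, `d2 = (1 - ratio) * D`,
#' and the noiseless effect is the `fa` solving
#' `d1 / Dx1(fa) + d2 / Dx2(fa) = true_ci`,
#' where `Dx_i(fa)` is each agent's solo dose for that effect. The left
#' side is strictly decreasing in `fa`, so the root is unique; it is found
#' by bracketed root-finding on (1e-9, 1 - 1e-9). `true_ci = 1` is exact
#' Loewe additivity (the null against which synergy is judged); values
#' below/above 1 generate synergistic/antagonistic mixtures. Noise is then
#' applied on the transformed scale exactly as in
#' [simulate_single_agent()]. `true_ci` may also be a function of the
#' total dose, for dose-varying interaction profiles.
#'
#' @param fit1,fit2 Component truths as [me_fit] objects (e.g.
#'   `me_fit(dm, m)`).
#' @param ratio Fraction of component 1 in the total dose, in (0, 1).
#' @param doses Total mixture doses (mg/mL, > 0).
#' @param true_ci Target combination index (> 0), or a function
#'   `function(dose) -> ci`.
#' @inheritParams simulate_single_agent
#' @return A tibble with columns `agent_id`, `replicate`, `dose` (total),
#'   `fraction_affected`, plus columns `d1`, `d2` with the component split.
#' @export
simulate_combination <- function(fit1, fit2, ratio, doses, true_ci = 1,
                                 noise_sd = 0, replicates = 3, seed = NULL,
                                 agent_id = "mixture") {
  check_me_fit(fit1, "simulate_combination")
  check_me_fit(fit2, "simulate_combination")
  check_fraction(ratio, "ratio", open = TRUE)
  if (length(doses) == 0 || any(doses <= 0)) abort("doses must be positive and non-empty")
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")

  ci_at <- if (is.function(true_ci)) true_ci else function(dose) true_ci

  fa0 <- vapply(as.numeric(doses), function(D) {
    target <- ci_at(D)
    check_number(target, "true_ci", positive = TRUE)
    loewe_fa(ratio * D, (1 - ratio) * D, fit1, fit2, target)
  }, numeric(1))

  grid <- tidyr::expand_grid(
    replicate = seq_len(replicates),
    tibble::tibble(dose = as.numeric(doses), fa0 = fa0)
  )
  y <- log10(grid$fa0 / (1 - grid$fa0))
  fa <- with_seed_if(seed, {
    yy <- y + stats::rnorm(nrow(grid), 0, noise_sd)
    10^yy / (1 + 10^yy)
  })
  tibble::tibble(
    agent_id = agent_id,
    replicate = grid$replicate,
    dose = grid$dose,
    d1 = ratio * grid$dose,
    d2 = (1 - ratio) * grid$dose,
    fraction_affected = fa
  )
}

# unique fa in (0,1) with d1/Dx1(fa) + d2/Dx2(fa) = ci; the sum is strictly
# decreasing in fa (both Dx_i increase), so a sign change brackets the root
loewe_fa <- function(d1, d2, fit1, fit2, ci, eps = 1e-9) {
  g <- function(fa) d1 / compute_dx(fit1, fa) + d2 / compute_dx(fit2, fa) - ci
  lo <- eps
  hi <- 1 - eps
  g_lo <- g(lo)
  g_hi <- g(hi)
  if (!(g_lo > 0 && g_hi < 0)) {
    abort(sprintf(
      "no effect level in (0, 1) attains CI = %g at total dose %g: attainable CI range at this dose is (%.3g, %.3g)",
      ci, d1 + d2, g_hi + ci, g_lo + ci
    ))
  }
  uniroot(g, c(lo, hi), tol = 1e-12)$root
}

# run expr under a local seed without disturbing the caller's RNG stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(seed, expr)
  }
}
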