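#' Constant-ratio combination design at IC50 multiples
#'
#' Builds the dose grid for a two-agent constant-ratio combination
#' experiment: each agent is dosed at the same set of multiples of its own
#' IC50, so the agents' mixing ratio `ic50_1 : ic50_2` is identical at every
#' level. Level concentrations are nominal (pre-mix) values; equal-volume
#' mixing halves in-reaction concentrations, so the dilution factor is
#' recorded as metadata (default 1). The CI mathematics is dose-scale
#' equivariant, so this bookkeeping cannot change CI.
#'
#' @param ic50_1,ic50_2 Single-agent median-effect doses (mg/mL, > 0).
#' @param multipliers IC50 multiples; default `c(2.5, 2, 1, 0.5, 0.2)`.
#' @param agent_ids Character pair of labels.
#' @param dilution_factor Volumetric dilution applied on mixing (1 =
#'   concentrations as printed; 2 = equal-volume mixing halves each).
#' @return A tibble of class `ratio_design` with columns `multiplier`,
#'   `conc_1`, `conc_2` (mg/mL) and `total`; attributes `agent_ids`,
#'   `ic50s`, `ratio` (fraction of agent 1 in the total dose) and
#'   `dilution_factor`.
#' @examples
#' make_design(0.0723, 0.1079, agent_ids = c("bromelain", "amenthoflavone"))
#' @export
make_design <- function(ic50_1, ic50_2, multipliers = c(2.5, 2, 1, 0.5, 0.2),
                        agent_ids = c("agent_1", "agent_2"),
                        dilution_factor = 1) {
  check_number(ic50_1, "ic50_1", positive = TRUE)
  check_number(ic50_2, "ic50_2", positive = TRUE)
  if (length(multipliers) == 0) abort("make_design: `multipliers` must be non-empty")
  if (any(multipliers <= 0)) abort("make_design: multipliers must be > 0")
  stopifnot(length(agent_ids) == 2)

  out <- tibble::tibble(
    multiplier = as.numeric(multipliers),
    conc_1 = multipliers * ic50_1,
    conc_2 = multipliers * ic50_2,
    total = multipliers * (ic50_1 + ic50_2)
  )
  structure(
    out,
    agent_ids = agent_ids,
    ic50s = c(ic50_1, ic50_2),
    ratio = ic50_1 / (ic50_1 + ic50_2),
    dilution_factor = dilution_factor,
    class = c("ratio_design", class(out))
  )
}

#' Write a combination design as a compounds-by-multipliers CSV
#'
#' Rows are the two compounds, columns the IC50 multiples; concentrations
#' are rounded half-up to 4 decimals for the report (full precision lives
#' in the design object).
#'
#' @param design A [make_design()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  if (!inherits(design, "ratio_design")) abort("write_design: expected a `ratio_design`")
  ids <- attr(design, "agent_ids")
  wide <- tibble::tibble(compound = ids)
  for (i in seq_len(nrow(design))) {
    wide[[sprintf("x%g_ic50", design$multiplier[i])]] <-
      round_half_up(c(design$conc_1[i], design$conc_2[i]), 4)
  }
  readr::write_csv(wide, path)
  invisible(path)
}

#' Fit a fixed-ratio mixture as a single entity
#'
#' Fits the median-effect model to a mixture's dose-effect series, with
#' dose the *total* mixture dose, exactly as a single agent would be
#' fitted. The component doses at any total dose `D` are the constant-ratio
#' split `(ratio * D, (1 - ratio) * D)`; in particular the component doses
#' at the mixture's median effect sum to the mixture `Dm`. This
#' mixture-as-single-entity fit is what lets CI be evaluated over the whole
#' effect range (the Fa-CI curve) rather than only at observed doses.
#'
#' @param data Dose-effect points for the mixture (columns `dose` = total
#'   mg/mL, `fraction_affected`).
#' @param ratio Fraction of component 1 in the total dose, strictly in
#'   (0, 1). For an equal-IC50-multiple design this is
#'   `ic50_1 / (ic50_1 + ic50_2)` (see [make_design()]).
#' @param agent_ids Character pair naming the components.
#' @inheritParams fit_median_effect
#' @return A `combo_fit` object: an [me_fit] for the mixture plus `ratio`,
#'   `agent_ids`, and the component split `d1`, `d2` at the mixture median
#'   effect (`d1 + d2 == dm`).
#' @export
fit_combination <- function(data, ratio, agent_ids = c("agent_1", "agent_2"),
                            agent_id = NULL, band = c(0.005, 0.995),
                            average_replicates = FALSE) {
  check_number(ratio, "ratio")
  check_fraction(ratio, "ratio", open = TRUE)
  fit <- fit_median_effect(
    data,
    agent_id = agent_id, band = band,
    average_replicates = average_replicates
  )
  as_combo_fit(fit, ratio, agent_ids)
}

as_combo_fit <- function(fit, ratio, agent_ids) {
  fit$ratio <- ratio
  fit$agent_ids <- agent_ids
  fit$d1 <- ratio * fit$dm
  fit$d2 <- (1 - ratio) * fit$dm
  class(fit) <- c("combo_fit", "me_fit")
  fit
}

#' @export
print.combo_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf(
    "  mixture of %s : %s at ratio %.4g : %.4g\n  split at median effect: %.4g + %.4g mg/mL\n",
    x$agent_ids[1], x$agent_ids[2], x$ratio, 1 - x$ratio, x$d1, x$d2
  ))
  invisible(x)
}

#' Classify a combination index
#'
#' Maps CI values to `synergism` / `additive` / `antagonism`. Exact Loewe
#' additivity is CI = 1, but estimated CI is never exactly 1, so the
#' default uses a tolerance band in the CompuSyn tradition: CI below
#' `bands[1]` (0.9) is synergism, above `bands[2]` (1.1) antagonism,
#' between them additive. `strict = TRUE` restores the textbook
#' trichotomy (< 1, = 1, > 1).
#'
#' @param ci Combination index value(s), > 0. Vectorized.
#' @param bands Lower and upper additive band edges.
#' @param strict Use the strict `<1 / =1 / >1` trichotomy instead.
#' @return Character vector of labels.
#' @examples
#' classify_ci(c(0.5, 1.0, 6.76))
#' @export
classify_ci <- function(ci, bands = c(0.9, 1.1), strict = FALSE) {
  if (!is.numeric(ci) || anyNA(ci) || any(ci <= 0)) {
    abort("classify_ci: ci must be numeric and > 0")
  }
  stopifnot(length(bands) == 2, bands[1] <= bands[2])
  if (strict) bands <- c(1, 1)
  dplyr::case_when(
    ci < bands[1] ~ "synergism",
    ci > bands[2] ~ "antagonism",
    .default = "additive"
  )
}

#' Combination-index profile over the effect range
#'
#' Evaluates the Chou-Talalay combination index
#' `CI = (D)_1 / (Dx)_1 + (D)_2 / (Dx)_2`
#' across a grid of effect levels. At each `fa` the total mixture dose
#' comes from the mixture fit ([compute_dx()]), the component doses
#' `(D)_i` from the constant-ratio split, and `(Dx)_i` — the dose of each
#' agent needed *alone* for that effect — from the single-agent fits.
#' CI < 1 is synergism (less drug needed together than Loewe additivity
#' predicts), CI = 1 additivity, CI > 1 antagonism.
#'
#' @param combo A [fit_combination()] result.
#' @param fit1,fit2 Single-agent [me_fit] objects, in the order of
#'   `combo$agent_ids`.
#' @param fa Effect-level grid in (0, 1); default 99 points 0.01..0.99,
#'   suitable for Fa-CI plotting.
#' @param bands,strict Passed to [classify_ci()].
#' @return A tibble of class `ci_profile` with columns `fa`, `d_total`,
#'   `d1`, `d2`, `dx1`, `dx2`, `dri1`, `dri2`, `ci`, `label`.
#' @export
compute_ci <- function(combo, fit1, fit2, fa = seq(0.01, 0.99, by = 0.01),
                       bands = c(0.9, 1.1), strict = FALSE) {
  if (!inherits(combo, "combo_fit")) abort("compute_ci: `combo` must be a `combo_fit`")
  check_me_fit(combo, "compute_ci")
  check_me_fit(fit1, "compute_ci")
  check_me_fit(fit2, "compute_ci")
  if (length(fa) == 0) abort("compute_ci: effect grid `fa` is empty")
  check_fraction(fa, "fa", open = TRUE)

  d_total <- compute_dx(combo, fa)
  out <- tibble::tibble(
    fa = fa,
    d_total = d_total,
    d1 = combo$ratio * d_total,
    d2 = (1 - combo$ratio) * d_total,
    dx1 = compute_dx(fit1, fa),
    dx2 = compute_dx(fit2, fa)
  )
  out <- dplyr::mutate(
    out,
    dri1 = .data$dx1 / .data$d1,
    dri2 = .data$dx2 / .data$d2,
    ci = .data$d1 / .data$dx1 + .data$d2 / .data$dx2,
    label = classify_ci(.data$ci, bands = bands, strict = strict)
  )
  structure(
    out,
    agent_ids = combo$agent_ids,
    mixture_id = combo$agent_id,
    class = c("ci_profile", class(tibble::tibble()))
  )
}

#' Pointwise combination index at observed mixture doses
#'
#' Computes CI directly at observed (total dose, fa) mixture points,
#' without a mixture median-effect fit: the observed `fa` supplies
#' `(Dx)_i` through the single-agent fits and the observed dose is split
#' by the constant ratio. Useful when the mixture series is too irregular
#' to fit, at the cost of a CI value only at the doses actually measured.
#'
#' @param data Mixture dose-effect points (columns `dose` = total mg/mL,
#'   `fraction_affected` in the open interval (0, 1)).
#' @param ratio Fraction of component 1 in the total dose.
#' @param fit1,fit2 Single-agent [me_fit] objects.
#' @inheritParams compute_ci
#' @return A `ci_profile` tibble as in [compute_ci()].
#' @export
compute_ci_pointwise <- function(data, ratio, fit1, fit2,
                                 bands = c(0.9, 1.1), strict = FALSE) {
  require_columns(data, c("dose", "fraction_affected"), "compute_ci_pointwise")
  check_fraction(ratio, "ratio", open = TRUE)
  check_me_fit(fit1, "compute_ci_pointwise")
  check_me_fit(fit2, "compute_ci_pointwise")
  check_fraction(data$fraction_affected, "fraction_affected", open = TRUE)

  out <- tibble::tibble(
    fa = data$fraction_affected,
    d_total = data$dose,
    d1 = ratio * data$dose,
    d2 = (1 - ratio) * data$dose,
    dx1 = compute_dx(fit1, data$fraction_affected),
    dx2 = compute_dx(fit2, data$fraction_affected)
  )
  out <- dplyr::mutate(
    out,
    dri1 = .data$dx1 / .data$d1,
    dri2 = .data$dx2 / .data$d2,
    ci = .data$d1 / .data$dx1 + .data$d2 / .data$dx2,
    label = classify_ci(.data$ci, bands = bands, strict = strict)
  )
  structure(
    out,
    agent_ids = c(fit1$agent_id, fit2$agent_id),
    mixture_id = "pointwise",
    class = c("ci_profile", class(tibble::tibble()))
  )
}

#' Dose-reduction-index table
#'
#' The DRI of each component at effect level `fa` is
#' `DRI_i = (Dx)_i / (D)_i`: the fold reduction in that agent's dose the
#' combination permits while holding the effect. DRI > 1 is favorable
#' (less drug for the same effect — relevant to dose-limiting toxicity),
#' DRI < 1 unfavorable. The identity `CI = 1/DRI_1 + 1/DRI_2` holds at
#' every level.
#'
#' Component doses normally come from the mixture fit's constant-ratio
#' split. Alternatively, pass `d1`/`d2` (with `combo = NULL`) to supply
#' the component doses at the mixture median effect directly — the bypass
#' used for worked examples from published parameter tables, valid at
#' `levels = 0.5` where `(Dx)_i` is each agent's own `Dm`.
#'
#' @param combo A [fit_combination()] result, or `NULL` in bypass mode.
#' @param fit1,fit2 Single-agent [me_fit] objects.
#' @param levels Effect levels; default `c(0.5, 0.75, 0.9, 0.95)` (IC50,
#'   IC75, IC90, IC95).
#' @param d1,d2 Bypass mode: component doses (mg/mL) at each level,
#'   recycled to `length(levels)`.
#' @return A tibble of class `dri_table` with columns `fa`, `d1`, `d2`,
#'   `dx1`, `dx2`, `dri1`, `dri2`, `favorable1`, `favorable2`, `ci`.
#' @examples
#' br <- me_fit(0.0723, 0.6767, "bromelain")
#' am <- me_fit(0.1079, 0.4480, "amenthoflavone")
#' # worked example from published component doses at the median effect:
#' compute_dri(NULL, br, am, levels = 0.5, d1 = 0.2437, d2 = 0.3655)
#' @export
compute_dri <- function(combo, fit1, fit2, levels = c(0.5, 0.75, 0.9, 0.95),
                        d1 = NULL, d2 = NULL) {
  check_me_fit(fit1, "compute_dri")
  check_me_fit(fit2, "compute_dri")
  if (length(levels) == 0) abort("compute_dri: `levels` is empty")
  check_fraction(levels, "levels", open = TRUE)

  if (is.null(combo)) {
    if (is.null(d1) || is.null(d2)) {
      abort("compute_dri: supply `combo`, or both `d1` and `d2` for bypass mode")
    }
    d1 <- rep_len(d1, length(levels))
    d2 <- rep_len(d2, length(levels))
  } else {
    if (!inherits(combo, "combo_fit")) abort("compute_dri: `combo` must be a `combo_fit`")
    check_me_fit(combo, "compute_dri")
    d_total <- compute_dx(combo, levels)
    d1 <- combo$ratio * d_total
    d2 <- (1 - combo$ratio) * d_total
  }

  out <- tibble::tibble(
    fa = levels,
    d1 = d1, d2 = d2,
    dx1 = compute_dx(fit1, levels),
    dx2 = compute_dx(fit2, levels)
  )
  out <- dplyr::mutate(
    out,
    dri1 = .data$dx1 / .data$d1,
    dri2 = .data$dx2 / .data$d2,
    favorable1 = .data$dri1 > 1,
    favorable2 = .data$dri2 > 1,
    ci = 1 / .data$dri1 + 1 / .data$dri2
  )
  structure(
    out,
    agent_ids = c(fit1$agent_id, fit2$agent_id),
    class = c("dri_table", class(tibble::tibble()))
  )
}
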