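---
title: "Median-effect analysis and combination-index methods in combindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-effect analysis and combination-index methods in combindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combindex)
```

combindex quantifies two-drug combination effects under Loewe additivity
using the Chou–Talalay median-effect framework. This vignette is the
package's account of the science: the model and its assumptions, the
parameters that matter, how the synthetic-data generator works and what it
does *not* emulate, the numerical choices, and the design decisions taken
where the method as usually practised leaves room.

## The median-effect model

The dose-effect relationship is assumed to follow the median-effect
equation,

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m, \qquad f_u = 1 - f_a,$$

where $f_a$ is the fraction of the assayed activity affected (here,
fractional inhibition of an enzyme), $D_m$ is the median-effect dose — the
dose at 50% effect, i.e. the IC50 — and $m$ is the sigmoidicity
coefficient, a Hill-type shape parameter ($m = 1$ hyperbolic, $m > 1$
sigmoidal, $m < 1$ flat). The model is exact for ideal mass-action
systems and is used here, as in the field, as a working approximation for
enzyme-inhibition dose-response data.

Its key property is that the transform $y = \log_{10}(f_a/f_u)$ is linear
in $x = \log_{10} D$ with slope $m$ and intercept $-m \log_{10} D_m$. The
fit in `fit_median_effect()` is therefore ordinary least squares on the
transformed scale — the exact linearization known as the median-effect
plot — with

* $m$ = the OLS slope (standard error reported as `m_se`),
* $D_m = 10^{-\text{intercept}/m}$,
* $r$ = the signed Pearson correlation of the transformed points.

No nonlinear refit is performed: the linearized fit *is* the method being
implemented, and it keeps the estimator identical to what the classical
software computes. $r \ge 0.95$ is reported as a quality-control flag
(`r_ok`), never enforced: a failing $r$ marks data the framework considers
unreliable, but the decision to discard is the analyst's.

### Usability band

The transform diverges at $f_a = 0$ and $1$, so observed 0% and 100%
points carry no usable information on this scale. Points with
$f_a \le 0.005$ or $\ge 0.995$ are excluded before fitting (the band is an
argument; excluded points and their reasons are retained on the fit
object). The default half-percent band discards only points
indistinguishable from total non-effect/effect at ordinary assay
precision.

### Replicates

Replicate points enter the regression individually by default, preserving
the error structure and giving the slope its honest standard error;
`average_replicates = TRUE` fits dose-wise means instead. For a balanced
design the slope estimate is identical either way; the standard errors are
not.

## From raw kinetics to dose-effect points

The assay layer models a colorimetric kinetic read: enzyme activity is the
optical-density drop per minute over the kinetic window,
$(OD_0 - OD_t)/t$, and percent inhibition normalizes a sample's activity
by the negative control,
$100\,(A_{ctrl} - A_{sample})/A_{ctrl}$. Decisions taken here:

* **The window length `duration` is a required argument, no default.**
  Protocols in this assay family use both 5- and 15-minute windows and the
  two agree only for linear traces, so the choice is forced into the open.
* **Timestamps are matched within a tolerance** (default 0.25 min),
  because plate readers jitter timestamps; a missing window edge is an
  error naming the missing time.
* **Blanks are optional** and subtracted pointwise before the rate is
  taken; the default is none.
* **Negative inhibition (activation) is retained and flagged**, never
  clamped to zero, so downstream filtering is explicit and auditable.

## Combination analysis

### Constant-ratio design

`make_design()` builds the standard constant-ratio experiment: both agents
at the same multiples of their own IC50s (default multiples 2.5, 2, 1,
0.5, 0.2), so the mixing ratio $IC50_1 : IC50_2$ is identical at every
level. Concentrations are stored nominally, as a bench scientist would
print them; equal-volume mixing halves the in-reaction concentrations, so
the design carries a `dilution_factor` metadata field (default 1) rather
than silently rescaling. CI is invariant under any common dose rescaling,
so this bookkeeping cannot change the synergy call.

### Mixture as a single entity

The combination index at effect level $f_a$ is

$$CI = \frac{(D)_1}{(D_x)_1} + \frac{(D)_2}{(D_x)_2},$$

with $(D_x)_i$ the solo dose of agent $i$ reaching $f_a$ (from its
median-effect fit) and $(D)_i$ the component doses inside the mixture at
that effect. Evaluating CI *as a curve over the whole effect range* — the
Fa–CI plot — requires knowing the total mixture dose at any $f_a$, which
only a dose-effect model of the mixture itself provides. combindex
therefore fits the fixed-ratio mixture as a single entity with its own
$(D_m, m)$ (`fit_combination()`), the standard constant-ratio treatment;
`compute_ci_pointwise()` is provided as an alternative that computes CI
only at observed dose-effect points, with no mixture fit, when the mixture
series is not well described by the model.

For two agents sharing slope $m$, exact Loewe additivity is closed under
the model: the additive mixture is itself median-effect with the same $m$
and $D_m^{mix} = (\rho/D_{m,1} + (1-\rho)/D_{m,2})^{-1}$ at mixing
fraction $\rho$. The test suite uses this closure as an oracle.

### DRI and classification

`compute_dri()` reports $DRI_i = (D_x)_i/(D)_i$ at IC50/75/90/95 by
default, flagged favorable when $> 1$, and carries the identity
$CI = 1/DRI_1 + 1/DRI_2$ to machine precision. A *bypass mode* accepts
component doses directly at the median effect: published parameter tables
sometimes print component splits that are inconsistent with the nominal
design ratio, and the bypass makes explicit exactly which inputs produce
which worked-example values instead of guessing at the provenance of
printed numbers.

Classification uses a tolerance band, CompuSyn-style: CI below 0.9 is
synergism, above 1.1 antagonism, additive between. The textbook
trichotomy ($<1/=1/>1$) is available via `strict = TRUE` but is unusable
for noisy estimates, where CI is never exactly 1. The band is an
argument; 0.9–1.1 is the field's conventional "nearly additive" width.

### Mixing-ratio source

The pipeline derives the mixture ratio from the fitted single-agent IC50s
(`ratio = "from-ic50s"`), matching the equal-IC50-multiple design; an
explicit numeric ratio overrides it, because real datasets (including
published ones) sometimes report component splits that contradict the
nominal design.

## The synthetic-data generator

Because raw dose-effect points for this assay family are rarely deposited,
every stage is testable against simulated data with the statistical
structure the analysis assumes.

`simulate_single_agent()` draws, per dose and replicate,
$y = m \log_{10}(D/D_m) + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$, and maps back $f_a = 10^y/(1+10^y)$. Noise lives on the
transformed (log-odds) scale: that is the scale on which the fit is
linear, and it keeps every generated fraction strictly inside $(0,1)$. A
clipped raw-$f_a$ Gaussian mode exists for robustness testing. Defaults
are 3 replicates (a conventional in-vitro choice) and 10 log-spaced doses
spanning 0.005–1 mg/mL — a grid bracketing the bromelain-class IC50s used
throughout the examples.

`simulate_combination()` imposes a *true* combination index pointwise: at
total dose $D$ with split $(d_1, d_2)$, the noiseless effect is the root
of $d_1/D_{x,1}(f_a) + d_2/D_{x,2}(f_a) = CI_{true}$, found by bracketed
root-finding (the left side is strictly decreasing in $f_a$, so the root
is unique). $CI_{true} = 1$ generates exact Loewe additivity — the null
the whole framework tests against — and a function of dose may be passed
for dose-varying interaction. Noise is then applied on the transformed
scale as above. Generation is seeded and deterministic, and leaves the
caller's RNG state untouched.

**What the generator does not emulate:** day/batch effects and replicate
correlation (all noise is i.i.d.), heteroscedasticity on the raw percent
scale, dose-measurement error, systematic lack of fit (real curves need
not be median-effect), or plate-level kinetics artifacts. Passing
recovery tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to real-assay pathology.

### Simulation study sizes

The recovery study the package ships (tests and `scripts/acceptance.R`)
uses 200 replicate series of 10 doses at noise sd 0.1 — at that size the
median fitted $D_m$ and $m$ sit within a few percent of truth and the run
completes in seconds — and the same 200 at sd 0.05 for the
quality-control behaviour, where well over 90% of fits clear $r \ge
0.95$.

## Numerical choices

* **Log base 10 throughout.** Any consistent base gives identical
  $(D_m, m)$; base 10 matches how the plots are read.
* **Root-finding** for the Loewe inversion brackets $f_a$ in
  $(10^{-9}, 1-10^{-9})$ with `uniroot` at tolerance $10^{-12}$; an
  unattainable target CI is an error that reports the attainable CI range
  at that dose.
* **Saturation:** for doses so far above/below $D_m$ that $f_a$ is within
  machine epsilon of 1 (or 0), $1 - f_a$ is not representable and
  inversion is meaningless; the informative range $f_a \in (0.01, 0.99)$
  is where round-trip accuracy (better than $10^{-9}$ relative) is
  guaranteed and tested.
* **Report rounding** is half-up (4 decimals for concentrations, 2 for
  CI/DRI), matching how such tables are conventionally printed, with a
  $\sqrt{\epsilon}$ guard so decimal halves like 2.41475 round up despite
  binary representation; full precision is retained everywhere internally
  and in the JSON report.
* **Degenerate inputs** error early with names: fewer than two usable
  points (listing exclusions and reasons), identical doses, zero control
  activity, non-positive slope fits passed to inversion.

## Pipeline and reproducibility

`run_pipeline(analysis_config(...))` runs reading, fitting, CI, DRI and
classification in one pass, logs one line per stage with its parameters
(`verbose` adds per-point usability exclusions), and writes a versioned
JSON report (`schema_version: 1`) plus flat CSVs and the Fa–CI figure. The
report contains no timestamps, so identical config and input produce a
byte-identical report; every number in the human-readable outputs appears
at full precision in the JSON.

## Known limitations

* Two agents at a constant ratio only: no checkerboard designs, no
  three-way combinations, and no alternative reference models (Bliss
  independence, HSA, ZIP).
* The mixture-as-single-entity CI curve inherits the assumption that the
  mixture itself is median-effect; `compute_ci_pointwise()` is the
  fallback, at the cost of CI only at observed doses.
* Confidence intervals for CI/DRI are not computed; `m_se` and `r` are
  reported per fit, but uncertainty propagation through the CI algebra
  (e.g. by simulation) is left to the user.
* The assay layer assumes linear kinetic traces over the chosen window;
  no curvature correction or Michaelis–Menten modelling is attempted.
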