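---
title: "Modelling excess infant mortality over a declining secular trend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling excess infant mortality over a declining secular trend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excesstrend)
```

## The model

An annual vital-statistics series holds, per calendar year, the number of
live births and the number of infant deaths (or stillbirths). Internally
every rate is a proportion `deaths/births`; the per-1000 convention of
published tables is presentation only, because both the logistic floor and
the binomial variance formula operate on proportions. The time index is
`t = year − 1930`, fixed so that published trend coefficients remain
interpretable (it can be overridden for other data, but the package's
reference constants assume it).

The expected rate is a smooth *secular* decline with superimposed
bell-shaped *excess terms* inside the linear predictor
`η(t)`:

* family `model1`: `E[y] = α + (1 − α)·plogis(η)`, `η = β₁ + β₂t + Σ bells`.
  The floor `α` is the rate the decline approaches as `t → ∞`; `β₂ < 0` is
  the logit-scale annual decline.
* family `model2`: `E[y] = exp(η)`, `η = β₁ + β₂t + β₃t² + β₄t³ + Σ bells`.
* family `model3`: `model2` with one bell designated as a war-time term, so
  series spanning the 1940s can be modelled without truncation.

Each bell is `(a/t)·exp(−(log t − μ)²/(2σ²))`: as a function of time it is
proportional to a lognormal density with log-scale location `μ` and width
`σ`, so it rises from zero, peaks at the lognormal mode `t = exp(μ − σ²)`,
and decays. The mode, converted to a calendar year by adding the origin, is
the "peak year" the package reports. Placing the bells *inside* the linear
predictor (rather than adding them to the rate) is a deliberate reading of
the model's printed form; the "excess rate" shown in plots is the derived
quantity observed minus undisturbed rate.

Two structural options mirror published analyses: width ties force two
bells to share one `σ` ("equal half-widths"), reducing the free-parameter
count by one per tie; and pulse/step intervention dummies absorb reporting
breaks — for German stillbirths, a pulse in 1994 and a level shift from
1995 capture the changed stillbirth definition.

### What "undisturbed" means

The expected count E over a window uses the full-data fit with all excess
amplitudes set to zero. Under `model3` the war-time bell is *kept* in the
baseline by default: it represents a disruption before the usual 1950–2000
estimation window, where its mass is negligible, and zeroing it would
distort the pre-1950 baseline; `zero_ww2 = TRUE` flips this. Intervention
dummies are zeroed by default (they model reporting artefacts, not the
decline). The alternative tradition — fitting a Poisson log-linear trend
with the window excluded and extrapolating across it — is deliberately kept
as a separate tool (`fit_loglinear_trend()`), because the two definitions
of "expected" must not be conflated.

## Estimation

`fit_model()` minimises the binomial-variance weighted residual sum of
squares `Σ (obs − fit)²/(fit·(1 − fit)/births)`. The weights are fully
iterated: an inner Levenberg–Marquardt solve (via `minpack.lm`) runs with
variances frozen at the current fitted values, the variances are then
recomputed, and the cycle repeats until the relative deviance change is
below 10⁻⁸ (25 cycles at most). Full iteration makes the result independent
of the starting weights; a `one_shot` mode (variances frozen once, from the
observed rates) is kept for sensitivity checks and for tests that need a
fixed, externally reproducible objective.

The *deviance* is defined as this weighted (Pearson-type) residual sum of
squares evaluated at the converged fit — the only definition consistent
with reporting overdispersion as `deviance/df` alongside F-tests of the
form `(dev₀ − dev₁)/df₁/OD`. Residual df is observations minus free
parameters; a tied width counts once, which reproduces published df
bookkeeping (e.g. a three-bell `model1` with one tie has 11 free
parameters: 69 observations give df = 58, 85 give df = 74).

Standard errors come from the unscaled weighted-Jacobian covariance
`(JᵀJ)⁻¹`, treating the binomial variance as known; `od_scale_se = TRUE`
inflates them by `√OD` for series with substantial extra-binomial
variation. Whether published standard errors were OD-scaled is not
something the package takes a position on; both are available. The
covariance solve equilibrates columns first, because polynomial (`t³`) and
bell columns differ by many orders of magnitude and would otherwise defeat
the inversion numerically.

### Initialisation and local minima

Overlapping bells riding on a misfitted trend create genuine local minima;
the single largest failure mode is a spurious bell parked at the end of the
series absorbing late-year trend misfit. The initialisation therefore works
on the link scale, where bells are additive:

1. a trend-only fit (closed-form link-scale regression, then a short
   weighted refinement);
2. orthogonal matching pursuit: candidate bells on a fixed grid of log-time
   locations (spacing 0.07) and trial widths {0.06, 0.12, 0.2} are added
   one at a time, each stage choosing the candidate that minimises the
   weighted link-scale residual sum of squares with the trend and all
   amplitudes refit in closed form, preferring placements that keep every
   amplitude positive;
3. for `model1` the provisional floor runs over a small grid of fractions
   of the minimum observed rate, since the logit link is very sensitive to
   the floor in the late, low-rate years.

The pursuit is deterministic, and `fit_model(init = NULL)` polishes the
best few pursuit results in full, keeping the lowest deviance. After
fitting, terms are relabelled in time order (a pure relabelling of the same
curve, skipped if it would violate a tie); without this, equivalent fits
differing only by term permutation would look like disagreement.
`stepwise_fit()` hedges similarly: each refinement is fitted both from the
previous fit plus one new bell seeded at the largest positive link-scale
residual, and from a fresh pursuit, keeping the better.

Bounds: widths are kept above 10⁻³ (a bell narrower than that is
indistinguishable from a single-year dummy at annual resolution) and the
floor is confined to `[0, min observed rate]`. One published width is
printed with a negative sign; since `σ` enters only as `σ²` the absolute
value is stored in the reference constants.

## Model selection and intervals

`f_test()` implements the overdispersion-scaled F comparison exactly as
defined above, with the refined model's `OD` computed from its deviance and
df (not from any rounded intermediate), referred to the upper tail of
`F(df₁, df₂)`. Upper-tail p-values are used throughout: the deviance drop
from adding a term is one-sided by construction, and this convention
matches the printed comparisons. No multiplicity correction is applied
across stepwise stages, mirroring the source analyses; `stepwise_fit()`
reports every stage rather than stopping, so the analyst sees the whole
deviance path.

`profile_ci()` fixes one parameter on trial values, re-optimises all
others, and brackets where the profiled deviance exceeds its minimum by
`OD·qF(level; 1, df₂)` — the scaled-objective analogue of a profile
likelihood interval. The search walks outward from the estimate in units of
the Wald SE and bisects; it is deterministic, and in a quadratic
(linear-model) limit it reproduces the Wald interval exactly. A profile
that fails to bracket within ±10 SE returns the reached bound with an
open-interval warning. Deterministic profiling was chosen as the primary CI
route over simulation-based intervals precisely so that coverage can be
tested reproducibly; a parametric bootstrap would be the natural
cross-check where the two disagree.

The interval for windowed excess deaths follows the slope-fixed-refit
construction: the model is refitted with `β₂` fixed at each profile bound
(all other parameters free), the expected count E is recomputed from each
refit's undisturbed trend, and the implied O−E and O/E at the two bounds
form the interval. The slope is profiled because it is the parameter that
controls where the baseline sits under the bells, hence the dominant source
of uncertainty in E.

Peak-year intervals use the delta method on `(μ, σ)` with their fitted
covariance (`g = exp(μ − σ²)`, gradient `(g, −2σg)`); a tied term uses its
master width's estimate and covariance entries. How the corresponding
published intervals were computed is not stated; the delta method is the
deterministic default here, and a bootstrap would again be the natural
cross-check.

## The synthetic-data generator

`simulate_series()` draws death counts around a true rate curve:
binomially, or beta-binomially when `dispersion > 0`. The beta-binomial
uses the intraclass-correlation parameterisation — variance
`n·p(1−p)·(1 + (n−1)ρ)` — because it nests the binomial at ρ = 0 and keeps
deaths below births by construction. Real pooled series show
overdispersion of order 10–40 at 10⁵–10⁶ births per year, i.e. ρ of a few
times 10⁻⁵; the generator's default is ρ = 0 (pure binomial) because the
recovery and coverage experiments are defined under binomial noise, and
dispersion is switched on explicitly where a test needs it. Births are
constant, per-year, or a log-linear decline with lognormal jitter — enough
to emulate post-war birth trends without claiming demographic realism (no
maternal-age structure, no cohort effects).

Noise-free reference fixtures (`make_reference_fixture()`) evaluate the
packaged published estimates and round `deaths = round(rate·births)` —
rounding, not truncation, for a symmetric error of at most `1/births` on
the rate. Exact-recovery tests fit these fixtures from the automatic
initialisation and demand the generating parameters back to 10⁻³ relative
error with near-zero deviance. What such tests show is that the optimiser
finds the truth when the model is exactly right and noise is negligible;
they say nothing about misspecification on real data, where the shape of
the assumed secular trend is unverifiable — the central caveat of any
excess-mortality decomposition of this kind.

## Problem sizes and numerical conventions in the test suite

The coverage experiment uses 100 seeded binomial simulations of a 69-year
pooled-European-style series at 10⁶ births/year, checking that the 90%
profile interval for `β₂` covers the truth 84–96 times and that the first
peak year is unbiased to ±0.3 years. The optimiser-versus-brute-force check
runs on an 8-point, one-bell toy with fixed one-shot weights, comparing
objective values to 10⁻⁶ relative against a grid-plus-Nelder-Mead
minimiser. Stillbirth-style runs use a single bell plus the 1994/1995
dummies over 1950–2020. These sizes keep the default suite quick while
exercising every code path end to end.

Other conventions: observed rates are clipped to `(10⁻¹⁰, 1 − 10⁻¹⁰)` only
on the link scale during initialisation (never in the fit itself); fitted
rates outside `(0, 1)` are reported, not clamped; duplicate years are
rejected while year gaps are allowed and simply absent from the fit (no
imputation), matching series with missing war years. For stillbirth series
the denominator is live births by default — the natural choice when
stillbirth counts are reported alongside live-birth tables — and is
configurable, since sources differ on this.

## Limitations

The decomposition is only as good as the assumed secular family; a smooth
trend misfit is absorbed by the bells (or vice versa), and nothing in the
data can fully distinguish the two. Inference treats years as independent
given the trend — no autocorrelation-robust errors. The stepwise F-tests
are unadjusted for selection. And the package deliberately stops at
estimation: it attaches no causal interpretation to any excess term.
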