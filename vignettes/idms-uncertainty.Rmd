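---
title: "Isotope-dilution quantification and its uncertainty budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-dilution quantification and its uncertainty budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmsquant)
```

## The measurement problem

Isotope dilution mass spectrometry quantifies an analyte by spiking the
sample with an isotopically labeled analogue and measuring the signal ratio
of the two isotopologues, here written throughout as r = A1/A2 (analyte
signal over label signal). Because analyte and label behave identically in
extraction, chromatography and ionization, the ratio is robust against
losses and matrix suppression — but the *instrument's* ratio response may
still be biased by a multiplicative factor. Both estimators in this package
are constructed so that this factor cancels:

* **Exact-matching double IDMS**: a sample blend and a calibration blend,
  prepared to nearly the same ratio, are compared as a ratio of ratios,
  `w_X = w_Zc (m_Y/m_X)(m_Zc/m_Yc)(R_B/R_Bc)`. The estimator is evaluated
  in exactly this grouping (`emd_mass_fraction()`), and
  `emd_matching_check()` flags ratios outside the 0.95–1.15 matching window
  inside which the design's bias cancellation works best.
* **Matched standard addition IDMS**: increasing amounts of an unlabeled
  reference solution (content `w_Z`) are added to sample + spike blends.
  Linearizing each blend to `x_i = m_z/m_x`, `y_i = (m_y/m_x) r_i` puts the
  instrument factor into both the slope and the intercept of the straight
  line `y = a1 x + a0`, so the content `w_X = (a0/a1) w_Z` is free of it.
  Molar masses and isotopologue amount fractions cancel in `a0/a1` for the
  same reason, which is why `msa_mass_fraction()` never needs them.

The y-axis convention deserves a note: in terms of the blend's isotopologue
*amount* ratio (label over analyte, the "inverted" ratio), the linearized
ordinate is `(m_y/m_x)` divided by that ratio. With ratios stored as
observed A1/A2 this is exactly multiplication; the package stores A1/A2
everywhere and keeps the inversion inside `linearize_general()`, which is
the only place it matters.

The regression is *unweighted* ordinary least squares with a free
intercept. This is a deliberate choice: the binary blend participates as an
ordinary x = 0 point rather than pinning the intercept, and no weighting by
the per-blend ratio uncertainties is applied. Weighted or errors-in-variables
fits change the coefficient estimates away from the values a bench analyst
obtains from the standard linearized fit, and the shipped worked examples
only reproduce under plain OLS. Outliers are never removed automatically:
`msa_fit(series, exclude = ...)` reports an explicitly excluded refit next
to the full one.

## Uncertainty: GUM and Monte Carlo

`model_spec()` couples a set of uncertain inputs (value, standard
uncertainty u, number of repeats n) to a deterministic model function. Two
evaluators consume it:

* `gum_budget()` — first-order propagation. Sensitivities are central
  finite differences with step `max(|x|, 1) * 1e-6`; all models here are
  smooth, well-scaled rational functions of their inputs, so this step is
  far below any curvature scale while staying clear of cancellation noise.
  The budget reports, per input, the sensitivity, the variance contribution
  `(c_i u_i)^2` and its index (share of the combined variance); indices sum
  to 1 by construction and the tests assert it to 1e-9.
* `monte_carlo()` — all inputs drawn as independent Gaussians, the model
  re-evaluated per draw. For the standard-addition model that means the
  regression is *re-fitted in every draw*, which is what makes the output
  distribution of `w_x` skewed (below). Summaries use the sample sd (n − 1)
  and type-7 linear-interpolation quantiles. Draws on which the model fails
  (a slope that is zero or negative carries no addition signal) are rejected
  and counted, never clipped — clipping would distort exactly the tails the
  simulation exists to measure; more than 1% rejections attaches a warning.

**Repeat scaling.** When an input's u summarises n repeat injections, the
standard error of its mean is `u/sqrt(n)`. The two evaluators default
differently, and this is intentional:

* `gum_budget(repeat_scaling = TRUE)` works with `u/sqrt(n)`, matching how
  published budget tables fold the factor into the printed sensitivity
  coefficient (0.58 for n = 3, 0.71 for n = 2). Contributions and indices
  are identical either way; `budget_report()` prints the folded layout for
  side-by-side comparison with such tables.
* `monte_carlo(repeat_scaling = FALSE)` draws with the per-observation u.
  This reproduces the dispersion conventions of the worked examples this
  package ships, whose Monte Carlo summaries (for example the intercept
  2.0534 ± 0.0355 of the matrix-sample series, and the 95% interval
  [0.961, 1.030] of the cyanuric-acid solution series) are only obtained
  with unscaled draws. Both evaluators expose the flag, so either
  convention is one argument away.

Published per-input index columns for the nested-regression model should be
compared with care: tabulated budgets often assume a *flat* unit relative
sensitivity for every mass and ratio, whereas the true OLS sensitivities
carry the leverage of each blend's position on the addition line (an
interior blend's ratio can dominate the budget well beyond its flat-c
share). The package always reports the finite-difference truth.

**Why the matrix-sample distribution is right-skewed.** In the matrix
experiment the reference additions are small relative to the sample mass,
so the design has little leverage: the slope a1 is uncertain (about 13%
relative) while the intercept a0 is tight. `w_x = (a0/a1) w_z` is then a
ratio with a noisy denominator: its distribution has a heavy upper tail,
its mean exceeds its median, and a symmetric "± U" statement would
misrepresent it. This is precisely what `monte_carlo()` on `msa_model()`
shows, and why the percentile interval is the honest summary there.

```{r skew}
mcs <- monte_carlo(msa_model(mel_pt_series()), n_draws = 5000, seed = 42)
tidy(mcs)
```

## Validation statistics

`matching_report()` summarises how constant the blend ratios are (the
matched design aims for near-constant ratios; an RSD above 2% is flagged,
advisory only). `target_ttest()` compares validation results built from a
single stock (target `w_X/w_Z = 1`) against that target with a two-sided t
test; with 8 values the 0.975-quantile critical value is 2.36 at 7 degrees
of freedom. `bias_report()` splits replicate dispersion into an instrument
component (within-blend repeats) and a preparation component (between
re-prepared sets), truncating a negative between-set excess to zero with a
flag. `linearity()` checks the straight-line response of area ratio versus
mass ratio (r² > 0.999 by default) with a free intercept, asserting
"through the origin" statistically (|intercept| < 3 se) rather than forcing
it.

## The synthetic experiment generator

`simulate_series()` realises a standard-addition experiment from a
`simulation_scenario()`: target masses with Gaussian weighing noise
(0.1% relative by default, the level of the shipped tables), ideal blend
ratios computed by inverting the addition line at the true content
(`r = (w_X m_x + w_Z m_z)/(w_Y m_y)`), Gaussian ratio noise (2% relative
by default, the repeatability the instrument typically delivers for these
analytes), an optional multiplicative instrument bias, and an optional
linear drift per injection, with injections running through the whole blend
sequence once per repeat. Two design builders are provided:
`default_blend_design()` (constant ~100 mg spike against ~500 mg sample,
additions 0/50/100/150 mg — the matrix-sample layout) and
`matched_blend_design()` (spike growing with the addition, keeping ratios
near-constant — the layout of the solution validation series and the
preparation the method itself prescribes).

What the generator emulates — and what it does not: gravimetric and
ratio-measurement noise, drift and bias are modelled; chromatographic peak
shape, ion statistics, carry-over and matrix-dependent ionization are not.
Passing simulation tests therefore validates the *estimators and the
propagation machinery*, not the chromatography in front of them.

Three numerical behaviours of the generator are worth knowing:

* With all noise off, the full pipeline returns the true content to
  machine precision, and a multiplicative instrument bias changes a0 and a1
  but not their ratio — both are regression tests.
* The drift model is linear in injection order. A consequence the tests
  assert as-is: *longer* sequences (more blends, at a fixed drift per
  injection) accumulate more drift and are more biased, not less. The
  protective value of denser designs in practice comes from drift
  diagnosis and shorter per-point spans, which this deliberately simple
  model does not represent.
* Coverage studies use `record_u = "nominal"` (the scenario's known noise
  levels as the uncertainty statement): k = 2 intervals then cover the
  truth at 94–95%. With empirical per-blend sds from 3 repeats (2 degrees
  of freedom each) the same intervals genuinely undercover, near 89% — the
  familiar small-sample effect of plugging noisy sd estimates into a
  normal-theory coverage factor. That is a property of few-repeat
  uncertainty statements, not of the propagation; analysts wanting honest
  coverage from few repeats should pool repeatability information across
  blends or runs.

## Problem sizes and determinism

The shipped examples are small (4 blends, 7 double-IDMS inputs), so the
deterministic results are instantaneous. Monte Carlo sizes used in the
package's own checks are 10^4 draws for the nested-regression models
(re-fitting 10^4 regressions takes a few seconds) and 10^6 draws for the
double-IDMS model, which is evaluated through a vectorized kernel. All
draws are reproducible: the same seed and draw count give bit-identical
results, and every stochastic entry point takes an explicit seed.

## Known limitations

* Inputs are assumed independent Gaussians; correlations (for example
  between masses weighed on the same balance) are not modelled.
* No adaptive Monte Carlo stopping rule; the draw count is the user's
  choice.
* The general overlap-corrected linearization is implemented, but the
  shipped examples all use the no-overlap simplification (isotopologue
  signals ≥ 3 Da apart), so the overlap path is exercised only by tests.
* Single-point (one-blend) IDMS calibration is not implemented.
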