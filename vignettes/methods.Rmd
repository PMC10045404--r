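---
title: "Methods: mechanistic and maximum-entropy suitability modelling in ecoclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic and maximum-entropy suitability modelling in ecoclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclim)
```

ecoclim implements two complementary species-distribution models for the
raisin moth (*Cadra figulilella*) and the scenario accounting that compares
them: a mechanistic Ecoclimatic Index (EI) engine driven by published
physiological parameters, and a correlative presence-only maximum-entropy
model tuned by the now-standard regularization-multiplier × feature-class
protocol. This vignette is the package's own account of the science: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic data generator does and does not
emulate, the numerical choices, and the known limitations.

## 1. The mechanistic engine

### Weekly climate

The engine operates on a 52-week year of 7 days (364 days). A 52-week
calendar makes all published weekly rates exact — stress rates are given in
week^-1 — at the cost of one calendar day. Monthly temperatures and
humidity are interpolated linearly between month midpoints to week
midpoints, periodically across the year boundary; monthly rainfall is
spread evenly over the days of each month and summed into weeks, with day
365 folded into week 52 so the annual total is conserved exactly. Linear
interpolation (rather than splines) keeps every worked example
hand-checkable; the smoothing it forgoes is far below the month-to-month
signal. The engine's humidity input is the unweighted mean of the 09:00 and
15:00 observations: the two observations bracket the daily cycle and no
principled weighting is available, so the midpoint is the neutral choice.
The same midpoint convention gives weekly mean temperature as
(tmin + tmax)/2; cold stress can optionally be driven by weekly tmin
instead (closer to frost logic) but defaults to tmean, since all published
threshold values were calibrated against mean temperatures.

### Soil moisture

Soil moisture is a single-bucket weekly balance in units of
soil-moisture-holding capacity:

sm_w = clamp( sm_{w-1} + (rain_w + irrigation_w − E_w) / capacity, 0, cap ),

with capacity 100 mm and a hard cap of 3.0. The cap sits just above the wet
stress threshold of the packaged species (2.5) so that wet stress can
engage while the state stays bounded; values above 1 represent
waterlogging. Evaporative demand is a deliberately simple bulk formulation,
E = max(0, c_et · tmean) · (1 − rh/100) · 7 mm/week with c_et = 0.8
mm · °C⁻¹ · day⁻¹ — linear in temperature, zero at saturation, with no
radiation or wind terms. Both `capacity_mm` and `c_et` are configuration
knobs for calibration. The annual cycle is iterated from sm = 0.5 until the
largest week-wise change between successive years falls below 1e-6
(maximum 500 years; non-convergence is an error signalling a pathological
configuration). Because the update is a clamped contraction, the converged
cycle is independent of the start value — a property the test suite checks
directly by spinning up from 0 and from 1.

Irrigation follows the agricultural top-up rule: a week with more than
10.5 mm of rain receives nothing; a drier week is topped up to the 10.5 mm
weekly threshold, equivalently at most 1.5 mm/day. Irrigation is added to
rainfall *before* the balance; whether the original tool nets it against
evaporation instead is not documented anywhere we could find, and adding it
as water input is the physically plain reading.

### Growth, stress, and EI

Temperature and moisture suitability are piecewise-linear trapezoids — zero
at or outside the outer thresholds, one on the optimal plateau — and the
weekly growth index is their product. The annual growth index is 100 times
the 52-week mean. Each single stress accumulates
100 · |rate| · max(0, exceedance) per week and is capped at 100; the
hot-wet interaction stress accrues the *product* of the temperature and
moisture exceedances, only in weeks where both gates are open. Rates are
taken by absolute value because published parameter tables mix signs. Later
versions of the commercial tool accumulate some stresses exponentially;
the linear form is used here because it is what the published parameter
values were presented with and it keeps closed-form worked examples (e.g.
52 weeks at 2 °C below a 0 °C threshold at |rate| 0.001 gives exactly
10.4).

EI multiplies the annual growth index by (1 − S/100) for each of the five
stresses, floors each factor at zero, and zeroes the result where annual
degree-days above DV0 fall short of the PDD generation requirement
(292 degree-days for the packaged species). The packaged parameter file
follows the published parameter table throughout; note that the source
narrative mentions a lower development threshold of 11 °C while its
parameter table lists 13 °C — the file ships the table value (13), and
users can edit the flat key-value file if they prefer the narrative one.

A binary "suitable" call requires a cut on the continuous EI ramp. The
default is EI ≥ 10 (closed lower bound), a conventional moderate-suitability
cut; the published area totals never state the threshold behind them, so
**every km² figure in this package is conditional on `ei_min`**, which is
exposed everywhere and defaults to 10. A three-class banding
(unsuitable / marginal / optimal, second cut at 30) is available for maps.

## 2. The maximum-entropy SDM

### Model and fitting

The model is the Gibbs density q(x) ∝ exp(β·f(x)) over a background
sample, with features f built from raw predictors: linear, quadratic,
pairwise-product, threshold and hinge classes, each rescaled to [0, 1] over
the background so that fits are invariant to affine changes of predictor
units. Hinge features use 20 quantile knots per variable by default
(forward and reverse pieces), threshold features 10 — counts are
configurable; they bound model flexibility the same way the original
tool's internal defaults do.

Coefficients minimise the L1-penalized negative presence log-likelihood
−mean_presence(η) + log Z̄ + Σ λ_j |β_j|, where Z̄ is the background mean of
exp(η) and λ_j = RM · β_class · s_j / √m (s_j the presence-sample standard
deviation of feature j, m the presence count; class base penalties default
to 1 for L/Q/P/T and 0.5 for hinge). This is the penalized
presence/background conditional-likelihood formulation — equivalent to the
classical maxent problem — rather than the original sequential algorithm.
Optimisation is cyclic coordinate descent with per-coordinate Newton steps,
soft-thresholding, and step-halving backtracking so the objective never
increases; convergence is declared when a full cycle improves the
objective by less than 1e-7 (tighter tolerances are available where
bit-level comparability matters). The regularized training gain is the
objective improvement over the uniform model, which makes all jackknife
gains non-negative by construction.

Percent contribution shares the cumulative per-update objective
improvements across each updated feature's source variable(s), normalized
to 100 — an attribution of the coordinate-descent trace that approximates
the original tool's path-dependent bookkeeping. Permutation importance
permutes one raw predictor at a time (seeded) and normalizes the drops in
training AUC. Predictions default to the cloglog transform
1 − exp(−e^H · q(x)), H the entropy of the fitted background distribution,
the standard [0, 1] map output; raw (exponential) and link outputs are also
available.

### Tuning and evaluation

The tuning grid crosses RM ∈ {0.5, 1, …, 4} with feature-class sets
{L, LQ, H, LQH, LQHP, LQHPT} — 48 combinations. Each combination gets (a)
an AICc from a full-data fit, with k = the number of nonzero coefficients,
n = the number of presences, and the presence log-likelihood under the
background-normalized density (AICc is undefined and the combination
excluded when n ≤ k + 1), and (b) cross-validated overfitting diagnostics —
the train-test AUC gap and the 10% training omission rate — under 4-fold
spatial-block cross-validation. Blocks split at the median latitude, then
at the median longitude within each half, which keeps the four groups equal
to within one point while remaining purely geographic. Selection is minimum
AICc, so the selected row reports delta.AICc = 0. The omission-rate
threshold uses the ceiling rule: with n training presences, the threshold
is the score just above the lowest ⌈0.1·n⌉ of them.

Supporting utilities mirror the standard preprocessing chain: greedy
distance thinning of occurrences (drop the highest-degree point within the
exclusion radius, seeded tie-breaks) — greedy is order-independent and
reproducible, though like the standard tools it does not guarantee the
maximum retained set; a greedy collinearity filter that keeps the
higher-contribution variable of any pair with |r| > 0.8, scanning in
descending contribution with alphabetical tie-breaks (the companion
"biological relevance" criterion of the original procedure is subjective
and is not encoded); and Horn's-method slope and aspect from an elevation
grid, with metric cell sizes from the geographic resolution, flat cells
assigned aspect 0, and edge rows handled by replication. A latitude
predictor can be used signed or absolute; published accounts are
internally inconsistent on this point, so both conventions are supported
and neither is asserted.

## 3. The synthetic world

The climate generator produces a deterministic, seeded monthly climatology:
annual-mean temperature declines linearly from the equator value at a
configurable lapse (default 27 °C and 0.6 °C per degree latitude), a
sinusoidal seasonal cycle flips phase across the equator, the diurnal range
is constant (10 °C), and rainfall follows a uniform, winter-wet or
summer-wet regime. The defaults — winter-wet regime, 800 mm/yr, baseline
humidity 70% — were chosen once to make a Mediterranean-type world, the
climate where the raisin moth is actually at home: wet mild winters
recharge the soil bucket, dry warm summers draw it down, and the engine
produces a subtropical-to-temperate suitable band whose poleward edge is
limited by temperature. Predictor rasters are Gaussian-smoothed white noise
rescaled to plausible bioclim-style magnitudes, the latitude raster is
exact, and slope/aspect derive from the synthetic elevation field. Presences
are drawn cell-weighted without replacement from a known logistic truth
surface (one record per location, as after thinning), with the intercept
solved to hit a target prevalence.

What the synthetic world does *not* emulate: spatial covariance structure
of real climate (orography, continentality, coastlines), humidity
seasonality, interannual variability, observation error and sampling bias
in occurrences, and the real correlation structure among bioclim
predictors. Passing tests therefore demonstrate that the algorithms are
implemented correctly and respond to controlled signals in the documented
direction — not that the package reproduces published global maps, which
would require the original climate archives.

Directional climate-change checks use a domain whose suitable band is
temperature-limited — cold edge inside the domain, warm edge outside (e.g.
latitudes 25–60°) — because that is the regime in which warming
unambiguously expands range; on a whole-globe domain, warming also degrades
the equatorward flank (heat and hot-wet stress), and the net area change is
a balance of the two edges, exactly as in published projections.

## 4. Problem sizes and reproducibility

The test suite and the acceptance script run on deliberately small worlds —
grids of a few hundred cells, tuning fixtures of 50–80 presences against
600–1500 background points with reduced hinge/threshold knot counts, and
recovery simulations of 267 presences (200 training after the 75/25 split)
against 5000 background on an 80 × 80 lattice, averaged over five seeds —
sizes chosen so the full pipeline, including the 48-combination tuning
grid, completes in seconds while every statistic retains enough data to be
meaningful. Every random quantity flows from an explicit seed; the pipeline
fans a single global seed out to fixed per-stage seeds so stages are
individually reproducible, and generators restore the caller's RNG state.
The oracle tests compare the vectorised engine against an independent
naive per-week loop on 1000 random weekly series at 1e-12, and the
coordinate-descent fitter against a generic quasi-Newton optimizer on the
same objective.

## 5. Known limitations

* The soil-moisture and evaporation formulations are documented surrogates:
  the commercial mechanistic tool's internal hydrology is unpublished, so
  absolute EI values here are not interchangeable with its output, even
  though the growth/stress/EI composition follows the published form.
* Diapause, radiation and substrate indices are not implemented (the
  raisin-moth parameterisation itself omits diapause); population dynamics
  and biotic interactions are out of scope.
* Stress accumulation is linear with a cap; exponential accumulation modes
  are not provided.
* Area totals depend on the EI (or probability) threshold, which published
  accounts leave unstated; percent changes are computed from unrounded
  areas, and printed reference figures are internally inconsistent at their
  stated precision (their abstract and results sections round differently).
* Climate and raster I/O is long-format CSV; binary geospatial formats
  (NetCDF, GeoTIFF) are not read or written.
* The maxent implementation aims for statistical, not bit-level,
  equivalence with the original Java tool; percent contribution in
  particular is attribution of a different (coordinate-descent) fit path.
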