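---
title: "Methods: spatial interpolation and health-risk mapping of groundwater arsenic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial interpolation and health-risk mapping of groundwater arsenic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asriskmap)
```

## The problem

Household-well surveys of groundwater arsenic produce a few hundred to a
few thousand point measurements with three awkward statistical features:
the concentrations are strongly right-skewed (means of ~10 ug/L with
maxima in the hundreds), a substantial fraction falls below the assay
detection limit, and nearby wells are correlated over kilometers. Health
authorities nevertheless need *maps*: which 1 km cells exceed the WHO
drinking-water guideline, where the lifetime cancer risk from ingestion
is unacceptable, and where the water is unfit for irrigation or
aquaculture.

`asriskmap` implements that workflow end to end: two competing spatial
interpolators — geostatistical ordinary kriging (OK) and a
coordinate-regression neural network trained with Levenberg–Marquardt
(the "BPNN") — compared by concentration-ordered three-fold
cross-validation, with the winning concentration surface converted into
USEPA carcinogenic and non-carcinogenic risk layers.

## Preprocessing

Concentrations are log10-transformed before any spatial modelling.
Skewed environmental concentrations are approximately log-normal;
normality of the transformed values can be checked with
`normality_pvalue()`, a Lilliefors-corrected Kolmogorov–Smirnov test
(chosen because the null parameters are estimated from the data; the
base is fixed at 10 throughout the package so that variogram sills, mse
goals and RMSEs are all in log10 units). Non-detects enter at half the
detection limit (0.45 ug/L for a 0.9 ug/L limit), the conventional
single-value substitution; they participate in splitting, fitting and
training at that value.

Cross-validation folds come from `ordered_split()`: wells sorted by
descending concentration are dealt round-robin into sets A, B, C. With
heavy skew a random split can put most of the extreme wells in one fold;
the ordered deal guarantees set sizes differing by at most one and
near-identical concentration distributions (921 wells split exactly
307/307/307). Ties are broken by well id so the split is deterministic.

## The variogram and ordinary kriging

`empirical_semivariogram()` computes the method-of-moments estimator
\(\hat\gamma(h) = \frac{1}{2N(h)}\sum [Z(x_i+h)-Z(x_i)]^2\) over
distance bins. Defaults: `max_lag` is half the maximum pairwise
distance, `bin_width = max_lag/15`, and bins with fewer than 30 pairs
are dropped — standard geostatistical practice. Pairs at zero separation
are excluded: duplicate-location variance belongs to the nugget, not to
a bin.

`fit_variogram_model()` fits the spherical, exponential or Gaussian
model by weighted least squares with pair counts as weights, parameters
bounded to \(c_0 \ge 0\), \(c > 0\), \(a > 0\). Because the
range/nugget objective surface is multimodal, the bounded trust-region
least-squares optimizer is launched from five ranges spread
log-uniformly across the lag span and the best weighted SSE wins. A
flat empirical variogram leaves the range unidentifiable; the fit then
returns the constant as the sill and flags
`range_identifiable = FALSE` rather than failing.

`ok_predict()` solves the standard ordinary kriging system with the
unbiasedness constraint. Three numerical conventions matter:

* \(\gamma(0) \equiv 0\) (the nugget applies only for \(h > 0\)), which
  makes OK an exact interpolator at sampled locations;
* the neighborhood is global — with at most a few hundred training
  wells per fold the dense solve is trivial and avoids search-radius
  artifacts;
* kriging is done in log10 space and back-transformed by a plain
  `10^(.)`, without a log-normal bias correction. The uncorrected
  back-transform underestimates the conditional mean; it is retained
  because both interpolators are compared in log space and the risk
  maps inherit a conservative (slightly low) concentration surface.
  This is a documented simplification, not an oversight.

Duplicate sample coordinates are averaged (with a warning) before the
solve; a singular system after a `1e-12` jitter raises an error naming
the likely cause.

## The neural interpolator

The BPNN is a deliberately from-scratch feed-forward network: inputs
are the two planar coordinates, hidden layers use the hyperbolic
tangent sigmoid, the output neuron is linear, and each neuron computes
`net = sum(X * W) - b` — the bias is *subtracted*, and the analytic
Jacobian carries the corresponding sign. Weights and biases initialize
uniformly in \([-1, 1]\).

Training is full-batch Levenberg–Marquardt: solve
\((J^\top J + \lambda I)\,\delta = J^\top e\), accept the step if the
SSE drops (then \(\lambda \leftarrow \lambda/10\)), otherwise raise
\(\lambda\) tenfold and retry — interpolating between Gauss–Newton and
gradient descent. Defaults: \(\lambda_0 = 10^{-3}\), factor 10, at most
1000 accepted epochs, convergence at mse \(\le 10^{-2}\) (log10 units).
When no damping value yields an improving step the iterate is at a
stationary point; `lm_train()` returns normally with
`status = "stalled"` and the best parameters rather than raising,
because a stall at a good minimum is the *usual* way LM terminates on
noisy data and callers (the architecture search, cross-validation)
must keep running. Genuinely non-finite behavior still errors.

Raw coordinates in meters would saturate tanh units immediately, so
inputs are centered on the training midrange and divided by the
half-extent per axis; the constants are stored in the model and applied
transparently at prediction. Targets (log10 concentration) stay
unscaled so the mse goal keeps its units.

`architecture_search()` scans candidate structures (even hidden sizes,
one or two hidden layers, e.g. `(2,2,1)` … `(2,12,12,1)`) by the same
three-fold scheme: train on two sets (3 random restarts, best training
mse kept), validate on the third, select by highest average validation
R² with RMSE as tie-break. The restart count is configurable since the
averaging convention over repeated runs is a free choice; restarts make
the selection robust to unlucky initializations.

## Model comparison

`cross_validate()` reports per-fold and average R² and RMSE for both
methods, computed on log10 concentrations — the scale both predictors
work on, and the only scale on which RMSEs of ~0.5 are meaningful for
data spanning 0.45–776 ug/L. R² is defined as
\(1 - SSE/SS_{tot}\) (the predictive coefficient of determination,
which can go negative), not squared Pearson correlation; the
alternative is a one-line change in `r_squared()` if ever needed.
Fold failures are recorded as `NA` and excluded from averages so a
single degenerate fold cannot silence the whole report.

## Risk assessment

With the default exposure parameters (IR = 1.4 L/day, BW = 64.5 kg,
ED = 30 yr, EF = 365 day/yr, AT = 79 × 365 = 28,835 days, RfD = 0.3
ug/(kg·day), CSF = 1.5 (mg/(kg·day))⁻¹):

* daily intake \(DI = C \cdot IR / BW\) (ug/kg/day),
* hazard quotient \(HQ = DI / RfD\), adverse effects possible when
  strictly above 1 (the boundary itself is acceptable),
* target risk \(TR = DI \cdot (EF \cdot ED / AT) \cdot CSF \cdot
  10^{-3}\), classified negligible below \(10^{-6}\), acceptable
  through \(10^{-4}\) (both boundaries inclusive in level 2), and
  unacceptable above.

Risk is always computed from back-transformed ug/L concentrations,
never from log values. Concentration classes use half-open
lower-inclusive intervals \([0,5)\), \([5,10)\), \([10,50)\),
\([50,\infty)\) — the published four-class lists for such maps are
often typeset inconsistently, and a map legend needs a partition, so
one is fixed here with the WHO 10 ug/L and irrigation 50 ug/L values
as interior cut points. Water above 50 ug/L (strictly) is unsuitable
for irrigation and aquaculture.

All classification boundaries are arguments, so a user who reads
"between" exclusively can flip a boundary without touching code.

## The synthetic-data generator

Real household-well records are rarely redistributable, so
`simulate_wells()` generates surveys with the statistical structure the
analysis assumes: a Gaussian random field in log10 space (dense
Cholesky of the variogram-implied covariance with `1e-10` jitter —
exact at ≤ ~2000 locations, no FFT machinery), exponentiated to
concentrations, and left-censored at the detection limit with
half-limit substitution. The default emulation target
(`default_field_spec()`) uses an exponential variogram with
\(c_0 = 0.015\), \(c = 0.05\), \(a = 15{,}000\) m and log10 mean
−0.05: kilometer-scale correlation, sill ≈ 0.065 log10² units, median
concentration near 0.9 ug/L so about half the wells are non-detects,
and back-transformed skewness well above 1 — the signature of
low-background alluvial surveys. Well placement is uniform by default
(an optional clustering fraction mimics settlement-driven sampling);
no claim is made that either matches any particular survey's design.

What the generator does *not* emulate: geology-driven trends and
anisotropy, non-stationary hot spots, measurement-error structure
beyond the nugget, and multi-aquifer mixing. Passing tests therefore
demonstrate correctness of the estimators under the stated stationary
model, not performance guarantees on any real plain.

## Problem sizes and determinism

The test suite and the acceptance script run the full stack at desk
scale: variogram recovery uses 30 fields of 500 wells; the
cross-validated comparison uses 600-well fields with a `(2,8,1)`
network, 120-epoch budget and one restart per fold — sizes at which
results stabilize while a complete run stays in the tens of seconds.
Every stochastic step takes an explicit seed (field realization, well
placement, weight initialization), derived seeds stay within 32-bit
range, and the pipeline stamps each run's artifacts with a
configuration hash and seed; two runs with the same configuration are
byte-identical.

## Known limitations

* No log-normal kriging bias correction (see above) and no universal,
  indicator or co-kriging; no anisotropic or nested variograms.
* The BPNN has no regularization or early stopping beyond the mse
  goal; with generous epoch budgets on small folds it can overfit —
  the cross-validation reports will show it, but nothing prevents it.
* Censored values enter as a point substitution; a likelihood-based
  treatment of censoring is out of scope.
* Exposure parameters are point values; no probabilistic (Monte Carlo)
  exposure assessment.
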