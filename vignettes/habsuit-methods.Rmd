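---
title: "Methods: presence-only suitability modelling with field validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only suitability modelling with field validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(habsuit)
```

This vignette is the package's own account of its statistical machinery:
the models, the assumptions they lean on, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical choices a maintainer would
otherwise have to reverse-engineer. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The modelling problem

Opportunistic occurrence records from public databases carry two systematic
distortions: spatial clustering of *effort* (records pile up where people
go, not where the species is) and no information about absence. The
workflow here addresses both, then asks a harder question than
cross-validation can answer: does the resulting map predict independent
field measurements — occupancy corrected for imperfect detection, and
ground-measured habitat quality?

## 2. Record preparation

**Cleaning.** Records with stated positional accuracy worse than 100 m
(the analysis-grid scale is 250 m) and records falling in cleared cells
are dropped. Out-of-extent records are counted and warned about rather
than raised as errors: a handful of stray coordinates should not abort a
regional analysis.

**Subregions.** Records and cells are split at the 500-m elevation
contour, on the premise that lowland-coastal and upland habitat are driven
by different processes. Tie-break: exactly 500 m is upland ("below 500 m"
is strict).

**Thinning.** `thin_occurrences()` shuffles the records under a seed, then
greedily accepts each record at least `min_dist` (inclusive boundary) from
every previously accepted one. This is maximal given the order — every
rejected record is within `min_dist` of some retained record — and the
random order makes replicates differ, which is exactly the between-set
variation the replicated-set design wants. Distances are planar Euclidean:
the package *requires* projected coordinates in meters and deliberately
does not implement geodesics; at regional extents the projection error is
orders of magnitude below the 2-km thinning scale.

**Collinearity screening.** `screen_predictors()` eliminates continuous
layers greedily in a caller-supplied priority order (keep the earlier,
more interpretable layer) whenever |Pearson r| over jointly valid cells
exceeds 0.75. Layer-wide cells, not presence locations, are used: the
point of screening is transferability of the fitted surface over the whole
region. Categorical layers are exempt; zero-variance layers are dropped
with a warning.

## 3. Sampling-bias surface

Survey effort is estimated from target-group records (here, arboreal
mammals sharing the focal species' detection process) pooled with the
focal records: a Gaussian kernel density (per-kernel normalization
`1/(2πσ²)`, truncation at 6σ where the kernel is below 1e-8 of its peak)
rescaled affinely so its minimum maps to 1 and maximum to 30. A constant
density field maps to all-1 — uniform *minimal* effort — because "no
gradient observed" should not inflate every cell's weight. The bandwidth
is not identified by the data; the default is 2 cell widths, enough to
smooth cell-level sampling artifacts without erasing the urban-coastal
effort gradient the surface exists to capture. The surface enters the
model only by weighting the background draw (`sample_background()`), the
standard target-group correction for presence-only models.

## 4. Maximum-entropy model

**Features.** Hinge features only. For each continuous variable, knots at
the `(1:k)/(k+1)` background quantiles (default k = 50 per direction,
capped by distinct values), with forward hinge
`max(0, (x−knot)/(x_max−knot))` and reverse hinge
`max(0, (knot−x)/(knot−x_min))`, so every feature is in [0,1] over the
background. Categorical variables contribute one indicator per observed
level. Hinge-only bases reproduce the flexible monotone-piecewise response
shapes that made this model family standard, while keeping the basis
linear in parameters.

**Objective and optimizer.** The fit minimizes
`−(1/m) Σ_pres λ·f + log Z(λ) + Σ_j β_j|λ_j|` with
`β_j = reg_multiplier × (0.5/√m) × sd_bg(f_j)` (m = presences; default
multiplier 2). Cyclic coordinate descent: each coordinate takes a
soft-thresholded proximal Newton step
`λ_j ← S(λ_j − g_j/h_j, β_j/h_j)` with `g` and `h` the gradient and
curvature of the smooth part, then halves the step until the exact
objective does not increase. Features with zero background variance are
frozen at 0 (their gradient never vanishes and they carry no
information). Convergence: a full cycle improving the objective by less
than `tol = 1e-5`, or 1000 cycles. The objective is therefore
non-increasing at every accepted step — a property the test suite asserts
on every fitted trace, and the practical safeguard against line-search
bugs.

**Outputs.** Raw `q` sums to one over the background by construction
(asserted to 1e-8). Logistic output `e^H q/(1+e^H q)` uses the entropy
`H` of `q`: a cell whose raw density equals the "typical" presence value
`e^{−H}` scores exactly 0.5. Percent contribution credits each accepted
step's objective improvement to the stepped feature's source variable —
the same training-path accounting used by the reference implementation,
with the same caveat that correlated variables trade credit. AUC uses
midrank ties (Mann–Whitney). Replicates: per replicate a random 75/25
presence split, a fresh biased background draw, fit, test-AUC, and a
full-grid logistic surface; surfaces are averaged cellwise, first over
replicates, then over thinned sets. Subregion models are fitted
independently and mosaicked at the 500-m contour with no seam blending —
which means each half carries its own logistic calibration, so cross-seam
comparisons are rank-valid, not level-valid (the pipeline test asserts
rank concordance with the generating truth for exactly this reason).

## 5. Occupancy model

Single-season likelihood per site:
`L_i = ψ_i Π_t p_it^{y_it}(1−p_it)^{1−y_it} + (1−ψ_i) I[no detections]`,
logit links on both ψ and p (the de facto default of the field's
software), missing occasions contributing no factor. Optimization runs
BFGS from five deterministic dispersed starts (constant vectors 0, ±1,
±2): small-sample occupancy likelihoods are multimodal, and deterministic
starts keep refits reproducible without an RNG. The coefficient
covariance is the inverse observed information from the numeric Hessian
of the *half* objective (neg2LL/2); a singular Hessian flags the model
rather than failing it.

Model selection: `AIC = −2LL + 2k`, ΔAIC, model likelihood
`exp(−ΔAIC/2)`, weights normalized over the candidate set, and a
ΔAIC < 2 support flag. The staged strategy — pick the detection structure
first against a constant-ψ null, then compare occupancy covariates with
that structure fixed — is implemented as pipeline sequencing, not
hard-coded into the fitter. `selection_table()` also accepts a plain
data.frame of (−2LL, k): printed tables are valid inputs, which is how
the acceptance script reproduces published arithmetic without the
unreleased field data.

Goodness of fit: Pearson χ² over detection-history frequencies with sites
pooled into cohorts sharing a covariate-and-missingness pattern (each
site its own cohort under continuous covariates), a parametric bootstrap
refitted from the MLE, `p = P(χ²_boot ≥ χ²_obs)`, and
`ĉ = χ²_obs / mean(χ²_boot)`. Fitted-ψ intervals use the delta method on
the logit scale, back-transformed, which keeps them inside (0,1).

## 6. Habitat quality from Point-Quarter transects

Density uses Pollard's unbiased estimator `λ̂ = 4(4n−1)/(π Σ r²)` (n
stations, r in meters), chosen over the Cottam–Curtis mean-distance
estimator for its unbiasedness under Poisson patterns — which the test
suite verifies by simulation at 300 stems/ha. Empty quadrants substitute
the 50-m search-truncation distance rather than being dropped: dropping
them biases density upward precisely at sparse sites. Per-species basal
area is `density × %occurrence × mean per-stem area`. The quality index
weights class basal areas by browse palatability (defaults 3/2/1/0 for
primary/secondary/tertiary/unsuitable) and multiplies by
`1 + 0.1 × (class-1/2 richness − 1)` capped at 1.5. The published index's
exact formula lives in unavailable supplementary material, so this is a
documented, fully overridable stand-in with the properties the published
description states: zero without browse trees, monotone in primary-browse
basal area, rewarding browse diversity.

## 7. The synthetic world

`gen_landscape()` builds standardized Gaussian random fields (white noise
circularly convolved with a Gaussian kernel of scale `correlation_length`
cells — default 16, i.e. 4 km at 250-m cells) plus quantile-thresholded
categorical layers (8 soil-like codes, 4 fire-like codes 0–3). True
suitability is `plogis(−2.5 + 1.5 z₁ + 2 max(z₂,0) − z₃)`. The intercept
−2.5 is a deliberate, frozen choice: it right-skews the suitability field
so high-suitability cells are rare pockets (roughly 13–16% of area above
0.6) holding a large share of presence draws — the regime the motivating
study reports, and the regime in which presence-background discrimination
is actually attainable. A symmetric world (intercept near 0) has most of
its area at middling suitability and a Bayes-optimal AUC near 0.66 — no
estimator could be "good" there, so a green discrimination test would be
unreachable and a red one uninformative.

`gen_occurrences()` draws cells proportional to suitability × observer
bias and jitters within the cell. `gen_histories()` stratifies sites over
four suitability quantile strata (the very-high/high/moderate/low field
design), draws occupancy with logit-linear ψ (default intercept −2,
slope 4) and nightly detections with per-trip p (defaults 0.43/0.36/0.30,
the published trip-wise estimates), and can inject failed recorders
(all-missing rows, dropped like real failed deployments).
`gen_transects()` simulates homogeneous Poisson forests of qualifying
trees (dbh > 20 cm, lognormal around a 35-cm median, log-sd 0.3) in a
60-m-buffered transect window and measures the quadrant geometry exactly;
the class-1/2 species share rises linearly with suitability (5→55% for
class 1 across the suitability range).

What the generator does **not** emulate: spatially autocorrelated
*residual* occupancy (ψ depends on suitability only), detection
heterogeneity beyond trip, non-Poisson tree clumping, species
misidentification, and GPS error beyond the stated accuracy field. A
green end-to-end test therefore establishes that the estimators recover
the stated generating process at field scale — not that any of those
field complications are handled.

## 8. Scale choices in the tests

The published design (5 sets × 20 replicates × 10,000 background points,
50 knots) fits comfortably on a workstation but not in a CI budget, so
the pipeline and acceptance tests shrink the *free* scale knobs
(background 600–1,500, knots 6–10, 1–2 sets) while keeping the *stated*
design quantities (65 sites, 7 nights, ψ = 0.5, p = 0.32 recovery at 63
sites, 200 transects at 300 stems/ha, 20 discrimination replicates,
2-km thinning verified on 1,000 points). Desk-scale test fixtures keep
the thinned-record *density* comparable to the full-scale design
(hundreds of records per subregion) — thinning a small world at full
distance starves any fitter, which is a statement about sample size, not
about the code.

## 9. Numerical conventions and degenerate inputs

- Rasters: row 1 is the northernmost row; cell-center registration;
  ESRI ASCII I/O round-trips values exactly; grids must match exactly —
  no resampling, ever.
- Suitability classes: left-closed right-open bins except the top bin,
  which absorbs values ≥ 0.8 (including 1.0).
- Thinning boundary: `≥ min_dist` is retained (inclusive).
- Constant bias field → all-1; constant predictor → no features
  (warning); all-nodata grid → error.
- Model JSON serialization stores doubles as 17-significant-digit
  strings, which round-trips IEEE doubles bit-exactly.
- Seeds: every stochastic entry point takes an explicit integer seed and
  restores the caller's RNG state afterwards; the pipeline derives all
  stage seeds from the single config seed.

## 10. Known limitations

- GeoTIFF is not supported (no reader available in the target
  environment); ESRI ASCII is the interchange format.
- The logistic output's level calibration differs across independently
  fitted subregions; mosaicked maps should be interpreted by rank, or
  recalibrated, across the seam.
- Percent contribution inherits the usual path-dependence caveat: with
  correlated predictors, credit allocation depends on the visiting
  order of coordinate descent.
- The GOF cohorting degenerates to one site per cohort under continuous
  covariates, which weakens the χ² approximation; the parametric
  bootstrap (rather than an asymptotic reference) is the mitigation.
- The habitat-quality index is a configurable stand-in, not the
  published supplementary formula.
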