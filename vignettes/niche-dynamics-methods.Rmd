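---
title: "Methods: niche dynamics, maximum-entropy models and virtual species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche dynamics, maximum-entropy models and virtual species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichedyn)
```

This vignette is the package's own account of the models and numerical
choices behind its functions. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The niche model

A species' realized climatic niche is represented as a density in a
two-dimensional climate plane. The plane is built once per analysis:
environmental variables, screened so that no retained pair has
|Pearson r| > `r_max` (default 0.90) over the background sample, are
standardized to zero mean and unit variance over the *pooled*
background points of both regions, and a PCA of that pooled sample
supplies the first two components. Pooling is essential: both regions'
occupancies must live in the same plane for cell-wise comparison, so
the grid extent is fixed to the pooled background score range and
shared by every `niche_grid`.

Within the plane, occurrences and background points are smoothed with
a product-Gaussian kernel evaluated on an `R` × `R` grid (default
`R = 100`; the kernel and resolution are conventions, and both are
exposed). Bandwidths follow Silverman's rule per axis. Occupancy is
corrected for climate availability,

$$ z = \frac{o/e}{\max(o/e)} , $$

with `o` the occurrence density and `e` the background density, so
that a species using climates in proportion to their availability has
flat occupancy. An uncorrected mode (`correct = FALSE`, `z = o/\max o`)
is available for sensitivity analysis.

**Finite supports from infinite kernels.** A Gaussian kernel density
is strictly positive everywhere, which would make "cells where the
background occurs" the whole grid. Both densities are therefore
truncated to zero below the smallest density found in any grid cell
that actually contains a point of the corresponding sample — a
deterministic, data-driven cut with no free parameter. The truncated
background support is the 100% climatic envelope; the 75% envelope
keeps envelope cells whose background density is at or above the 25th
percentile of the positive densities, restricting comparisons to
analogue climates. Expect `z = 0` wherever `e = 0` and the 75% envelope
nested in the 100% one; both are invariants under test.

## Overlap, similarity and the S/U/E decomposition

Overlap is Schoener's
$D = 1 - \tfrac12\sum_\text{cells}\lvert p_1 - p_2\rvert$ on the
normalized occupancies — symmetric, scale-invariant, 0 for disjoint
and 1 for identical niches.

The similarity test asks whether the observed D beats the overlap
expected if one niche sat at a random position in its region's
available climate. Each null replicate rigidly translates that grid's
occupancy to a uniformly random integer offset whose support stays
fully inside the region's 100% envelope (no wrapping, no truncation of
the density). The identity offset is excluded: the observed
arrangement already enters once through the plus-one estimator
$p = (1 + \#\{D_\text{null} \ge D_\text{obs}\})/(1 + n_\text{reps})$,
which also keeps p in (0, 1]. Translation preserves niche shape while
randomizing position; its price is that a niche whose support fills
its envelope has nowhere to go — `similarity_test()` then errors, and
the `niche_dynamics()` wrapper reports `NA` for that direction with a
warning (this happens by construction in the background-clipped
"unfilled" scenario). The two directions relocate the invaded and the
native grid respectively.

Stability, unfilling and expansion are computed inside the union of
the chosen envelopes of the two regions (default the 75% envelopes;
100% available). With supports defined as `z > 0` — optionally after
discarding the lowest `support_quantile` fraction of density mass,
default 0 —

* E = invaded mass outside the native support, over invaded mass;
* S = 1 − E, exactly;
* U = native mass outside the invaded support, over native mass.

## The maximum-entropy distribution model

The SDM is a Gibbs density over the background sample. Features are
each variable and its square (pairwise products optional), min–max
scaled to [0, 1] over the background; features constant over the
background are dropped with a warning. Coefficients maximize

$$ \sum_{\text{presences}} \lambda\!\cdot\!f(x)
   \;-\; n_\text{pres}\,\log\!\!\sum_{\text{background}}\!\! e^{\lambda\cdot f(x)}
   \;-\; \beta \sum_j s_j\,\lvert\lambda_j\rvert , $$

with $s_j$ the feature SD over the presences and β one global
regularization knob (default 1). The objective is concave; the L1 term
is handled exactly by the split $\lambda = a - b$, $a, b \ge 0$, and
L-BFGS-B with analytic gradients (gradient tolerance 1e-6, tight
`factr`; non-convergence is an error carrying the optimizer
diagnostics). Concavity means every start reaches the same objective —
a property the tests check to 1e-6 from random starts. As β → ∞ all
coefficients collapse to exact zeros and the background suitability is
uniformly 0.5.

Reported suitability is the classic logistic output with prevalence
0.5: `plogis(λ·f(x) − log Z + H)`, H the entropy of the fitted density
over the background. Evaluation splits presences 75/25 per replicate,
refits on the training share, and scores AUC by the rank
(Mann–Whitney) formula with ties counting one half, against the
background sample; final prediction surfaces are the mean of the
replicate projections (10 replicates in the tests and acceptance
script, 100 by pipeline default). Projection onto another region uses
the *training* normalization constants, unclamped; cells outside the
training range of any variable are flagged in an extrapolation mask.
Binary ranges use the nearest-rank 10th percentile of presence
suitabilities; in the config-driven pipeline both reciprocal models
are thresholded at the invaded-range occurrences, matching the
convention of reporting a single comparison region. Areas use the
spherical-degree cell area
`(111.320 cos φ Δλ)(110.574 Δφ)` km² — transparent and adequate at
regional scale, in place of an equal-area reprojection.

## Occupancy profiles

A profile integrates a suitability map over a covariate raster
(altitude in the shipped workflow): suitability mass per `bin_width`
covariate bin (default 100 m), normalized to one, with the
suitability-weighted covariate mean computed before binning. Two
profiles are compared by the maximum absolute difference of their
cumulative curves. A suitability profile has no natural sample size,
so the KS statistic is primary; the p-value applies the asymptotic
two-sample formula with an effective n equal to the number of bins
carrying mass in either profile and is flagged advisory
(`p_value_advisory`).

## The virtual study system

`make_landscape()` builds each climate layer from seeded Gaussian
white noise smoothed with a Gaussian filter (`spatial_smoothing`
cells, edge-renormalized). Because smoothing collapses the effective
degrees of freedom, raw smoothed fields show large spurious
correlations; the fields are therefore empirically orthonormalized
(QR, jointly with the deterministic north–south gradient that is added
to every layer at SD 0.3) and mixed through the Cholesky factor of the
target correlation matrix, so pairwise layer correlations equal
`layer_correlation` by construction. Layers are standardized; units
are background-SD units throughout.

The virtual species is a product of per-axis Gaussians
(`suitability_surface()`), sampled proportionally to suitability at
cell centres, one record per cell (`sample_occurrences()`).
`make_scenario_pair()` wires the ground-truth situations: *conserved*
(same niche, independent landscapes), *unfilled* (the invaded stack is
clipped to the central `truncation_quantile` climate envelope of the
native background on every niche axis) and *expanded* (the invaded
niche centre is shifted). Scenario stacks also carry an `alt` layer
(metres, affine in `env1`, floored at sea level): a topography proxy
collinear with climate, which the |r| > 0.90 screening removes from
modelling — mirroring how altitude behaves among real bioclim
variables — while remaining available as the profile covariate.

**Study conditions.** The documented conditions, used by the
acceptance tests and `scripts/acceptance.R`, are: 120 × 120-cell
landscapes, three climate layers, smoothing 4 cells, inter-layer
correlation 0.3, niche breadth 0.75 background-SD per axis, 1000
occurrences and 10,000 background points per region, `R = 100`, 99
similarity replicates. Breadth 0.75 describes a moderately specialized
species: wide enough that its occupancy samples much of the climate
plane, narrow enough that the translation null has room to relocate
the niche. Two deliberate departures:

* The SDM parameter-recovery fixture uses breadth 0.5. On these
  landscapes the *true* suitability of a breadth-0.75 species — the
  optimal score — separates suitability-weighted presences from
  background only weakly (the niche covers most of the available
  climate), so discrimination tests there would measure the simulator,
  not the model. At breadth 0.5 discrimination is attainable and the
  test verifies the fitted model approaches that ceiling.
* The projection-asymmetry check emulates incomplete colonization the
  way it occurs in real invasions: the invaded *background* is intact,
  but occurrences are truncated (`clip_suitability()`) to an interior,
  low-altitude-biased climate window on every niche axis, so the
  realized invaded niche is nested in the native one in all fitted
  dimensions. Clipping the background instead (the "unfilled"
  scenario) removes the presence/background contrast a maxent fit
  needs, and one-sided truncation leaves the invaded model predicting
  conditions below the native range's own 10th-percentile cut — both
  fail to produce the nested ranges the check is about.

**What passing recovery tests does and does not show.** The simulator
emulates correlated, spatially autocorrelated climate with a
latitudinal trend and presence-only sampling proportional to
suitability. It does not emulate real covariance among 19 bioclim
variables, sampling bias, dispersal limitation, demography or
occurrence error; recovery under these conditions demonstrates the
estimators' correctness, not robustness to those field realities.

## Numerical notes and edge cases

* All randomness is seeded; every pipeline stage derives its stream
  from the one root seed, so reports are bit-reproducible.
* Raster convention: row 1 is the northernmost row; a point belongs to
  the half-open cell [x, x + cell) × (y − cell, y]; occurrence dedup
  keeps the first record per cell in input order.
* Correlation pruning drops the *later-ordered* member of the worst
  offending pair, iteratively, so results do not depend on the order
  pairs cross the threshold; zero-variance layers are removed first
  with a warning.
* Kernel bandwidths are floored at 1e-6 so single-cell occurrence
  clusters (zero spread) remain valid input.
* The 75% envelope uses "at or above" the 25th percentile so a
  constant background density degenerates to the 100% envelope rather
  than to an empty set.
* With fewer than 5 occurrences bandwidth estimation is refused; with
  fewer than 10 presences the SDM is refused; an empty test split is
  an error rather than a silent skip.

## Known limitations

Only two ordination axes are supported; backgrounds are bounding
boxes, not polygons; there is no reprojection between coordinate
systems; hinge/threshold features and clamping are deliberately
absent from the SDM; KS inference on profiles is advisory by design.
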