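# nichedyn

Quantifying climatic niche dynamics between the native and invaded
ranges of an introduced species.

## The problem

When a species is introduced to a new region, ecologists ask whether it
keeps its native climatic requirements (niche conservatism) or occupies
new conditions. `nichedyn` implements the standard ordination-based
workflow for that question, aimed at invasion biologists and
biogeographers working with presence-only records and gridded climate:

1. **A common climate space.** Climate variables are screened for
   collinearity (one member of every pair with |r| > 0.90 is dropped)
   and a PCA is fitted to the pooled background environments of both
   regions; the first two components define the niche plane.
2. **Gridded occupancy densities.** Occurrence records are projected
   into that plane and smoothed with a Gaussian kernel on an R × R grid
   (Silverman bandwidths), as is the background climate; occupancy is
   corrected for climate availability, `z = (o/e) / max(o/e)`, within
   the region's climatic envelope.
3. **Overlap and its decomposition.** Niche overlap is Schoener's
   `D = 1 − ½ Σ |p₁ − p₂|`, tested against a null in which one niche is
   rigidly translated to random positions inside its envelope.
   The comparison is decomposed, within analogue climates (the 75%
   envelopes), into **stability** S (invaded density inside the native
   niche), **expansion** E = 1 − S (invaded density outside it) and
   **unfilling** U (native density outside the invaded niche).
4. **Reciprocal distribution models.** A regularized maximum-entropy
   presence/background model (linear + quadratic features, L1 penalty
   `β · s_j`, logistic output) is fitted in each range, evaluated by
   replicated 75/25 train/test AUC, averaged over replicates, projected
   onto the invaded region, thresholded at the 10th presence
   percentile, and the two binary ranges are compared (areas in km²,
   inclusion fractions).
5. **Occupancy profiles.** Predicted suitability is integrated along an
   altitude raster into a normalized profile whose weighted mean
   summarizes the predicted elevational centre; profiles are compared
   with a Kolmogorov–Smirnov statistic.

A virtual-species simulator (correlated, spatially autocorrelated
climate layers; Gaussian niches; suitability-weighted sampling)
generates study systems with known ground truth — conserved, unfilled
or expanded niches — so every estimator can be validated by parameter
recovery. Rasters are exchanged as plain-text ESRI ASCII grids,
occurrences as CSV (`lon,lat,year,source`).

## Worked example

An end-to-end run on a simulated conserved-niche invasion (two
120 × 120-cell regions, three correlated climate layers plus a derived
altitude layer, 1000 occurrences and 10,000 background points per
region):

```r
library(nichedyn)

cfg <- analysis_config(n_occurrences = 1000, n_background = 10000,
                       sdm_replicates = 10, seed = 1)
rep <- run_analysis(cfg)
print(rep)
#> == Niche dynamics ==
#>   D = 0.838 (P 0.020 / 0.010), S = 0.965, U = 0.037, E = 0.035
#> == SDM ==
#>   AUC test: native 0.798, invaded 0.779; thresholds 0.249 / 0.276
#>   areas (km2): from invaded 213222, from native 215895; inclusion 99.4% / 98.1%
#> == Profiles ==
#>   weighted means: native model 1220, invaded model 1220; KS D = 0.003
```

Read: the two realized niches overlap strongly (D = 0.84) and far more
than chance (both directed similarity tests P ≤ 0.02); the invaded
niche is almost entirely inside the native one (S = 0.97) with
negligible unfilling and expansion — the generator's conserved ground
truth, recovered. The reciprocal distribution models are
near-symmetric: similar test AUCs, near-identical predicted areas,
mutual inclusion ≈ 99%, and indistinguishable altitudinal profiles
(KS D ≈ 0), as expected when nothing differs between ranges but the
landscape realization. `autoplot()` renders niche grids, suitability
maps and profiles; `tidy()`/`glance()` return the numbers as tibbles.

`run_analysis()` is also scriptable from a shell via
`inst/scripts/nichedyn-run.R --config cfg.yaml --out DIR`, with the
configuration (all defaults above: r_max 0.90, R = 100, 75% envelope,
β = 1, 75/25 split, 10th percentile, 99 similarity replicates, 100 m
bins) stored as YAML.

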