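---
title: "Methods: multi-metric climate exposure for protected-area networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-metric climate exposure for protected-area networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climrisk)
```

## The problem

Climate change displaces climatic conditions across landscapes. Where the
displacement is fast, species must either move with their climate envelope
or tolerate novel conditions; where conditions become unlike anything
nearby, neither option may exist. Protected-area (PA) networks were
designed on the assumption of a stationary climate, so two questions
recur in conservation planning: *how exposed is each place* — and each PA
and species — *to projected change*, and *are PAs more or less exposed
than comparable unprotected land?*

`climrisk` answers these with four complementary per-cell/per-polygon
metrics on gridded yearly climate data, plus matched PA-vs-control
comparisons and species-level aggregation. No single metric captures
exposure: a cell can face slow isopleth movement (low local velocity) yet
have its nearest future climate analog hundreds of kilometres away (high
analog velocity), or vice versa. The package treats the joint pattern as
the object of interest.

## Data model and assumptions

All computation happens on a **regular equal-area projected grid** with
cell size in km (continental European studies use 1 km ETRS89-LAEA).
Geographic (lon/lat) rasters must be reprojected upstream; the package
does planar geometry only, because every formula below is stated in km.
Cell centers sit at `origin + (index − 0.5)·cell_size`; all polygon/cell
membership uses **cell-center containment**, which keeps zonal medians and
protection fractions unambiguous at the native resolution.

Two variables describe general climatic conditions: mean annual
near-surface temperature (°C) and annual precipitation (mm/yr). Each is a
yearly stack over a 30-year baseline (1981–2010) and a 30-year future
period (2041–2070), per scenario × Earth-System-Model (ESM) combination.
The **climatology** of a period is the per-cell multi-year mean; the
baseline also supplies the per-cell interannual SD (sample SD, n−1) used
to standardize the magnitude and analog metrics. Nodata handling is
mask-first: a cell missing in any year is excluded from all metrics before
any computation, so ocean/ice masks propagate identically everywhere.

## The metrics

### Temporal trend and spatial gradient

The **trend** (units/yr) is the per-cell OLS slope of value on calendar
year over the concatenated baseline + future series; the 30-year gap
between periods is simply absent from the predictor. A per-period mode
(average of the two within-period slopes) is available but non-default:
one regression across both periods uses all 60 observations and matches
the "change between periods" reading of the velocity numerator. Note a
subtlety the test suite pins down: for two flat blocks 10 → 13 with
midpoints 60 yr apart the concatenated OLS slope is 2700/58495 ≈ 0.046,
*not* 3/60, because the within-block year variance enters the denominator.
For any series that is actually linear through time the slope is exact.

The **gradient** (units/km) at a focal cell is the vector sum of west–east
and north–south components, each the mean of the adjacent-pair differences
inside the 3×3 neighborhood (up to 6 per axis) divided by the cell size.
Border cells use the neighbors they have; nodata neighbors are excluded.
On a planar field with slope *g* along x this yields exactly *g* at every
cell, including borders — the property the closed-form tests rely on.

### Local velocity

`v = slope / max(gradient, gradient_floor)`, in km/yr. The ratio is
singular on climatically flat terrain, so gradients below
`gradient_floor` (default 1e−4 units/km) are floored and the affected
cells flagged rather than emitting unbounded velocities. Per-variable
velocities keep the sign of the trend (a drying landscape has negative
precipitation velocity); the combined surface is `|v_temp| + |v_prec|`,
the form used for mapping and for the residence-time denominator.

### Analog velocity

For focal cell *i*, candidate cells *j* are those whose *future* climate
vector standardized by the focal cell's baseline interannual SD,
`(b_kj − a_ki)/s_ki`, has Euclidean norm ≤ `threshold_sd` (default 1.5).
The metric is the planar distance to the nearest candidate divided by the
elapsed time between climatology midpoints (`elapsed_yr`, default 60 for
1981–2010 → 2041–2070). The search radius defaults to 1500 km; cells with
no candidate inside it carry a distinct no-analog flag (they are reported,
not silently dropped — "blank spots" on maps). Standardizing by the
*focal* cell's SD (rather than the candidate's) follows the SED
definition; the choice matters only where variability changes steeply in
space.

The implementation walks Chebyshev rings outward from the focal cell with
early termination: a ring at index *r* contains no cell closer than
`r·cell_size`, so the scan stops once that bound exceeds the best distance
found. Ties at equal distance break by smaller dissimilarity, then by
row-major cell order, making results independent of scan order and
exactly equal to an exhaustive all-pairs search — an equivalence the test
suite checks cell-by-cell on seeded grids. Cells with zero interannual SD
cannot be standardized and are returned nodata with a reported count.

### Magnitude (SED)

`SED_i = sqrt(Σ_k (b_ki − a_ki)²/s_ki²)` over the two variables. It is
dimensionless, weights variables equally, and is invariant to jointly
rescaling changes and SDs — a property tested explicitly. Cells with zero
SD in any variable are nodata.

### Residence time

`RT = 2·sqrt(A/π) / gV`, the polygon's equivalent-circle diameter over its
mean within-polygon combined local velocity. Velocities below
`velocity_floor` (default 0.01 km/yr) are floored and flagged to avoid
infinities. The combined (absolute-sum) velocity is used for `gV` by
default — the polygon-level "how fast is climate moving here" summary —
with a temperature-only option, since the source analyses do not pin the
choice down.

## Ensembles, hotspots, overlay

Per metric and scenario, the ensemble is the per-cell mean and sample SD
across ESM members; a cell is valid only where all members are valid, and
partial validity (e.g. no-analog in one member) is reported as a separate
count layer. **Hotspots** are cells strictly above the 75th percentile of
an ensemble metric over all valid study-area cells, **coldspots** strictly
below the 25th (linear-interpolation quantiles; ties at a threshold belong
to neither mask, so masks are invariant to monotone transforms). The
overlay codes each cell by its subset of hot metrics (8 codes), a joint-
coldspot flag (all three metrics cold — candidate climate refugia), and a
distinct no-analog code. PA coverage is reported both cell-wise (share of
protected cells per category) and polygon-wise, with the deliberate
asymmetry that a PA *overlaps* a hotspot if any of its cells is hot but
*is* a coldspot only if all of its cells are jointly cold.

## Protected-vs-control comparison

Cells are **treated** if their PA overlap fraction exceeds 50%, **control**
below 5%, excluded between — so the contrast is between clearly protected
and clearly unprotected land. Within each biogeographic region a logistic
propensity model (main effects on standardized covariates) estimates the
probability of protection; treated cells are matched to unused controls by
nearest propensity, hardest-to-match (highest score) first, discarding
pairs whose score distance exceeds 0.25·SD of the region's scores. The
caliper is read as an *upper* bound on pair distance — the standard usage
— although the source description's wording ("too low") is ambiguous.
Balance is diagnosed per covariate with the standardized mean difference
(balanced at SMD ≤ 0.1) and globally with the C-statistic (rank AUC of
scores vs. treatment, folded at 0.5), reported before matching and after,
both on original scores and on scores refitted within the matched sample.
Outcomes are compared with a paired Wilcoxon signed-rank test (exact null
up to 25 informative pairs, tie-corrected normal approximation above;
zero differences dropped; all-zero comparisons flagged with p = 1).

## What the synthetic generators emulate

* `make_planar_series`: climate = planar spatial field + linear trend +
  iid Gaussian interannual noise. This makes every metric analytically
  known (trend *r*, gradient *g* ⇒ local and analog velocity *r/g*) and is
  the backbone of the closed-form tests. It does **not** emulate spatial
  autocorrelation of weather, topography, coastlines, or ESM covariance —
  so passing tests certify the *estimators*, not realism of any particular
  landscape.
* `make_protected_landscape`: five iid standard-normal cell covariates
  (two baseline-climate summaries, land cover, human footprint,
  elevation), protection assigned per cell by a Bernoulli draw from a
  logistic model on those covariates — protection is thereby *confounded*
  with the covariates, the situation matching is for. Overlap fractions
  are drawn consistently with the protected indicator, plus a 10% share of
  marginal (5–50%) cells that the treatment rule excludes. A linear
  covariate→outcome model (`outcome_model`) is included as an extension so
  that the *naive* treated-vs-control contrast is demonstrably biased; the
  calibration experiment instead uses the spec of the protection effect
  itself — a climate-derived magnitude surface plus an additive shift
  `effect_on_outcome` inside protected cells — so its null is exact.
  Polygons are non-overlapping discs and rectangles with analytically
  exact areas (rejection-packed; an infeasible packing errors out).
* `make_species_occurrences`: iid Bernoulli incidence with every species
  guaranteed ≥ 1 site (redraw; at occupancy 0, one uniformly chosen site).

All generators run under a private RNG stream derived from their seed and
leave the caller's RNG state untouched; identical parameters + seed give
bit-identical output.

## The calibration experiment

`calibration_replicate()` is one end-to-end replicate: noisy planar
climates → magnitude surface; confounded landscape → treatment labels;
logistic scores → greedy caliper matching → paired Wilcoxon on the
magnitude outcome (plus optional SMD/C-statistic diagnostics and an
additive protection effect). The study sizes were fixed in advance at a
96×96-cell landscape (≈ 2.1k matched pairs per replicate — large enough
that the SMD ≤ 0.1 criterion is a real test, since the SMD's sampling SE
is ≈ √(2/n_pairs) ≈ 0.03), with 2000 replicates for the type-I error of
the null protection effect and 200 each for effect recovery and balance
diagnostics. One caveat worth stating: when outcomes *do* depend linearly
on the matching covariates, the paired signed-rank test on matched pairs
is mildly conservative (measured ≈ 0.035 at nominal 0.05 over 6000
replicates) because matching induces positive cross-pair correlation in
the covariate component of the differences; with the protection-effect
null used here the test is calibrated.

## Numerical choices and degenerate inputs

* Sample (n−1) SD everywhere an interannual SD is needed.
* Quantiles: type-7 (linear interpolation); threshold ties excluded.
* Analog/matching tie-breaks are total orders (distance → dissimilarity →
  row-major; |Δscore| → control id), so every result is deterministic.
* Zero-SD cells, zero-gradient cells, zero-velocity polygons: masked or
  floored with flags, never silent infinities.
* Perfect separation in the propensity model is an error (no comparable
  controls exist); constant covariates drop out harmlessly.
* Empty polygon sets error in zonal operations; polygons covering no cell
  center yield NA with a warning; a region without controls is skipped
  with a warning.

## Pipeline and problem sizes

`run_pipeline()` chains the stages deterministically and stamps every
table with the MD5 of the run manifest (config + version + seed), so two
runs with one differing parameter are distinguishable and identical runs
are byte-identical. The default synthetic configuration (48×48 cells of
10 km, 2 variables × 2 periods × 30 years, 3 pseudo-ESM members, 12
polygons, 40 species) completes in a few seconds; the test-suite grids
(up to 100×100 for closed forms, 40×40 for the analog-oracle equivalence)
were chosen as the smallest sizes at which the checked properties are
non-trivial.

## Known limitations

* Planar distances only; inputs must be on an equal-area projection.
* Single-node, in-memory arrays; continental 1 km grids need tiling,
  which is out of scope here.
* The analog search treats each cell's climate as a continuous vector;
  class-based (discretized) analog definitions would give coarser
  distances.
* WDPA-style polygon cleaning (de-duplication, point buffering, coastal
  clipping) is an upstream contract, not re-implemented.
* The hotspot quartiles are study-area-wide; per-region quartiles would
  answer a different (relative-to-region) question.
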