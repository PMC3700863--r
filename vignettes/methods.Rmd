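---
title: "Methods: presence-only maximum entropy and range-shift metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only maximum entropy and range-shift metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmshift)
```

# The modelling problem

`sdmshift` estimates where climate is suitable for a species from
presence-only occurrence records — observations of where the species *was
seen*, with no usable information about where it is absent. The estimation
target is a probability distribution over the cells of an analysis grid:
given that a presence record occurred somewhere in the study region, how
likely was each cell? The package contrasts the environment at presences
with the environment over *background* cells sampled from the whole region,
the standard device for presence-only data.

Two assumptions matter and should be kept in mind when interpreting
outputs. First, records are treated as a (biased-correctable-by-thinning)
sample from the species' climatic niche; systematic observation effort that
concentrates records spatially violates this, which is why the record
filters exist. Second, projections to future climate assume the fitted
climate–occurrence relationship transfers in time (niche conservatism) and
that the species can reach any newly suitable cell (full dispersal). Both
are conventions of the climate-envelope literature, not facts.

# The record filters

Four rules clean the raw records, in any order (the filters commute and are
idempotent, which the test suite asserts):

* **Source screen.** Records flagged `bbs` (breeding-bird survey) or
  `ringing` are dropped. Survey and ringing sites produce very many records
  at fixed points and would dominate the spatial sample.
* **Season screen.** Migratory species keep only records dated April 15 –
  July 30 (the breeding window; other records trace migration routes, not
  breeding range). Resident species drop December 1 – January 31 (winter
  nomadism moves birds off their breeding ranges); this window wraps the
  year boundary. Both windows are inclusive at both endpoints: the printed
  calendar dates name days that belong to the window, and a symmetric
  convention is the only one that does not privilege an end.
* **Sample-size screen.** Species with 25 or fewer records (strictly
  `> 25` required) are excluded; below that a presence-only model is not
  worth fitting.
* **Thinning.** Multiple records in one grid cell collapse to a single
  presence cell (default on). Grid-based presence-only models treat the
  cell as the observation unit; duplicate records in a cell measure
  observer effort, not extra information about the niche.

The "records should be spread evenly over the study area" criterion used in
practice by atlas workers is judgment-based; the package instead *reports* a
measurable proxy — the fraction of 1°×1° blocks containing at least one
record (`coverage_fraction()`) — and does not enforce it.

# Bioclimatic variables

`derive_bioclim()` computes the 19 standard BIOCLIM summaries from monthly
tmin/tmax/precipitation, in the WorldClim dialect:

* Monthly mean temperature is `(tmin + tmax)/2`.
* BIO4 is `100 × sd` of the monthly means and BIO15 is
  `100 × sd(precip)/(1 + mean(precip))` — the `+1` guards division in arid
  cells. Both use the *population* standard deviation (divide by 12), and
  the test suite pins this down, because the sample/population choice
  changes BIO4 by ~4.5% and silently breaks cross-tool comparisons.
  An alternative dialect (ANUCLIM) defines BIO4 as a coefficient of
  variation; the WorldClim convention is used because WorldClim-distributed
  layers are what field studies in this region typically model with.
* Quarters are all 12 consecutive 3-month windows with December–January
  wraparound; ties between equally wet/warm quarters resolve to the
  earliest starting month, making the layers deterministic.
* Temperatures are handled in °C throughout, never the integer °C×10
  storage convention of distributed rasters; a reader that encounters
  scaled data must convert on load.
* A cell missing any of its 36 monthly values is `NA` in all 19 layers.

Masking to the study bounding box (`mask_to_box()`) sets cells whose
*centres* fall outside the box to `NA` and preserves the grid shape, so all
downstream layers stay aligned.

# Variable selection

With 19 strongly interrelated layers, collinearity makes weights
uninterpretable and destabilizes jackknife importance. `pearson_matrix()`
computes pairwise Pearson correlations over unmasked cells
(pairwise-complete; a zero-variance layer yields `NA`, treated as "no
evidence of correlation"). `eliminate_correlated()` then sweeps candidates
in a priority order, accepting a variable only if `|r| < 0.75` against every
already-accepted one. Exactly `|r| = 0.75` counts as correlated and
eliminates — the threshold names the boundary of "highly correlated", so the
boundary itself belongs to the eliminated side; the choice is documented
here because the opposite convention is defensible too.

Expert within-pair choice ("keep the biologically meaningful one") is
replaced by an explicit, reproducible priority list. The default puts the
eight variables most often retained for resident songbird models first
(BIO4, BIO1, BIO15, BIO12, BIO14, BIO8, BIO2, BIO3), then the rest in
ascending order. For migratory species `migrant_substitution()` swaps BIO1
→ BIO10 and BIO14 → BIO18: summer migrants only experience the warm-quarter
climate, so annual-scale variables are replaced by their warm-season
correlates. Correlations are computed on the current-period stack only —
the selection must be fixed before projection, and future layers are model
output, not observations.

# The maximum-entropy model

## Features

For each selected variable the model uses a linear and a quadratic feature
plus hinge features `max(0, v − k)` at 10 knots placed at the background
deciles. Every feature is min–max scaled to [0, 1] over the background,
and the scaling is stored: projection onto another climate stack reuses it
and *clamps* projected features to [0, 1], so the model never extrapolates
beyond its training range (the standard MaxEnt clamping behaviour; without
it, quadratic features can explode under novel climates). Hinge features
are only enabled when the training presence count is at least 15 — a
simplified form of MaxEnt's sample-size rules — because with very few
presences the hinge basis can chase individual records. Quadratic and hinge
features that are constant over the background are dropped; a constant
linear feature is kept as an all-zero column whose weight simply stays 0.

## Objective and optimizer

The model is the Gibbs distribution `q(x) = exp(λ·f(x))/Z` over background
cells maximizing entropy subject to (relaxed) feature-mean constraints,
equivalently minimizing the convex objective

$$-\frac{1}{m}\sum_{\text{presences}} \lambda\cdot f(x) \;+\; \log Z \;+\;
\sum_j \beta\, s_j\, |\lambda_j|,$$

with `s_j = sd(f_j at presences)/√m`. The per-feature scale makes the
penalty adaptive: features that vary a lot across the presences — whose
empirical means are noisy — are shrunk harder, and everything relaxes as
`1/√m` with more data. `β` (default 1.0) scales the whole penalty.

The optimizer is proximal gradient descent: a gradient step on the smooth
part followed by soft-thresholding for the L1 term, with backtracking line
search and a modest step-growth factor between iterations. Backtracking
guarantees the objective never increases — an invariant the tests assert on
every fit — and convergence is declared when the objective changes by less
than `5e-5` (default) within 1000 iterations; non-convergence returns the
model with a warning flag rather than an error. Tighter tolerances are used
in tests that compare against numerical oracles. The fit is deterministic
given its inputs; randomness enters only through background subsampling
(uniform, without replacement, up to 10,000 cells — all unmasked cells when
fewer) and the 75/25 train/test split, both seeded. Presence cells are
eligible as background: background represents available environment, not
pseudo-absence.

Degenerate cases worth knowing: if the presence feature means equal the
background means, the zero vector is optimal and the fitted distribution is
exactly uniform; if the presence mean of some feature equals its background
maximum and `β = 0`, the likelihood has no finite maximizer (the
distribution piles onto the extreme cells and the objective decreases
forever, ever more slowly) — the iteration cap and tolerance then act as
implicit regularization, which is one practical reason the default `β` is
positive.

## Outputs and evaluation

Suitability is reported on the logistic scale `p = c q′/(1 + c q′)` with
`c = exp(H)`, `H` the entropy of the fitted background distribution — a
monotone transform of `q` scaled so the uniform model scores 0.5
everywhere. AUC is rank-based (Mann–Whitney, midranks; ties count 0.5) and
is invariant under monotone transforms, so it does not matter whether raw
or logistic scores feed it; the package uses logistic scores against the
training background. Jackknife importance refits with each variable
excluded and alone, reporting training AUC per refit plus each variable's
share of `Σ|λ_j s_j|` as a percent contribution.

# Thresholding, richness, change metrics

The 10-percentile training-presence threshold is computed without
interpolation: sort the training-presence suitabilities ascending and take
the value at index `⌊0.1 m⌋ + 1`. At most `⌊0.1 m⌋` training presences fall
strictly below it, so training omission never exceeds 10% plus the
discreteness slack `1/m`. Binarization uses `≥`, keeping threshold-valued
cells (including the defining presences) on the presence side. Percentile
rules differ across tools (nearest-rank, linear interpolation); the
counting convention here is exactly reproducible and is asserted by
enumeration in the tests.

Richness maps are cellwise sums of per-species binaries; change maps are
`future − current`. Range-change metrics per species and period pair:

* **Overlap**: cellwise product map, and `100 × |both| / |current|`.
* **Area change**: `100 × (A_fut − A_cur)/A_cur` with cell areas weighted
  by `cos(latitude)`; between 36° and 42°N an unweighted count distorts
  relative area by up to ~8%, which is material next to reported changes of
  tens of percent.
* **Centroids**: cos-latitude-weighted means of presence-cell centres;
  displacement is the haversine distance on a sphere of radius 6371 km
  (projection-free; accurate to well under 0.5% at this spatial extent,
  where 1° of arc is 111.19 km).
* **Ellipses**: eigendecomposition of the 2×2 weighted covariance of
  presence-cell centres in a local tangent plane about the centroid
  (`x = Δlon · cos φ_c · 111.19` km, `y = Δlat · 111.19` km, with `φ_c` the
  *centroid* latitude — over a ≤ 6° latitude band the difference from
  per-cell scaling is negligible and the centroid-anchored plane keeps the
  covariance exactly centred). A single-cell range returns a zero matrix
  with a warning.
* **Turnover**: because "area keeping the same species across timelines"
  admits two readings, both are computed — chained pairwise retention
  (each period vs the previous) and all-timeline persistence (cells present
  in every period, as a share of the current range). Group summaries report
  the mean and *population* standard deviation across species; species with
  an empty current range are excluded from averages and logged.

# The synthetic-data generator

The generator exists so that every stage has a testable input with a known
answer. `make_climate()` builds monthly layers as deterministic structure
plus spatially autocorrelated noise: a linear latitudinal temperature
gradient (−0.8 °C per degree north), a sinusoidal seasonal cycle peaking in
July (amplitude 10 °C), a winter-peaking log-scale precipitation cycle, and
Gaussian-kernel-smoothed white noise with a configurable length scale
(default 3 cells) — the simplest controllable emulation of climate-field
smoothness. Temperature minima/maxima are built as a midpoint ± a strictly
positive half-range, so `tmax > tmin` holds by construction; precipitation
is log-normal, hence non-negative. Scenario perturbation is an additive
temperature delta and a multiplicative precipitation factor, which makes
oracle checks exact: BIO1 shifts by exactly the delta, BIO12 scales by
exactly the factor.

`sample_occurrences()` draws record cells from
`P(x) ∝ exp(w·z(x)) × bias(x)` with `z` the standardized bioclim variables
of a `truth_model()` and an optional Gaussian observer-bias kernel around
"popular site" cells; coordinates are jittered uniformly within the cell,
dates drawn uniformly from a configurable seasonal window (so the season
filters have something to cut), and source flags drawn from a configurable
mixture (default 90% casual, 5% BBS, 5% ringing, so the source filter is
exercised too).

What the generator does **not** emulate: topography and coastlines,
land-cover constraints, temporally correlated weather, GCM anomaly
structure, and the heavy spatial clustering of real citizen-science effort
beyond the simple bias kernel. Passing tests on synthetic data therefore
demonstrate that the algorithms are implemented correctly, not that the
ecological conclusions from any particular real dataset are right.

# Study conditions of the demo and tests

The demo (`demo_config()`) uses a 20 × 30 grid of 0.3° cells over
26–35°E/36–42°N, three species (a cool-adapted resident, `w(BIO1) = −2`; a
wet-adapted resident, `w(BIO12) = 1.5`; a warm-season migrant,
`w(BIO10) = 1, w(BIO18) = 0.8`), 200 records per species, and two scenario
families — A2a-like (+1.0/+2.0/+3.5 °C, ×0.95/0.90/0.85 precipitation) and
B2a-like (+0.8/+1.5/+2.5 °C, ×0.97/0.94/0.90) for 2020/2050/2080 —
magnitudes in line with mid-range coupled-model anomalies for Anatolia.
Because temperature decreases northward, warming pushes the cool-adapted
species' suitable climate north: the demo reliably shows a northward
centroid displacement growing along each scenario's warming path, with
overlap below 100%.

Parameter-recovery experiments use a 50 × 50 grid with linear features
only: recovery of a two-variable log-linear truth from 500 records is
required within 15% relative error, and the mean KL divergence of the
fitted from the true distribution (averaged over 10 replicate draws to
estimate its expectation) must decrease over sample sizes 50 → 200 → 1000.
These sizes keep the full suite comfortably fast while leaving no slack for
an incorrectly scaled gradient or penalty to hide.

# Known limitations

* Grid cells are the modelling unit; sub-cell structure and coastline
  partial cells are ignored, and cell areas use the cos-latitude
  approximation rather than exact spherical polygons.
* The optimizer is first-order; for very large feature sets (tens of
  thousands of hinge knots) a coordinate-wise or quasi-Newton scheme would
  converge in fewer passes. At the package's intended scales this is
  immaterial.
* No product or threshold features, no cumulative output format, and no
  novel-climate (MESS-style) diagnostics; clamping is the only
  extrapolation control.
* Alternative binarization rules (minimum training presence, max SSS) are
  not built in; `binarize()` accepts any threshold, so they can be supplied
  externally.
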