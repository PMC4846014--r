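---
title: "Presence-only roost-habitat modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only roost-habitat modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roosthab)
```

## The problem

Forest bats such as the endangered Indiana bat (*Myotis sodalis*) roost in
ephemeral snags scattered across heavily forested, rugged landscapes.
Protecting individual roost trees is impractical, so managers need
landscape-scale maps of *where roosting habitat is likely to occur*. The only
data usually available are presence records (telemetry locations of known
roosts) — there are no true absences — which calls for presence-only
modelling against a background sample of the landscape.

`roosthab` implements that workflow end to end: deriving terrain predictors
from a DEM, fitting maximum-entropy (maxent) presence-only models with linear
and quadratic features, comparing a balanced set of a-priori candidate models
by small-sample-corrected AIC, and producing an Akaike-weight-averaged
suitability map classified into suitable and optimal habitat.

## The maxent model

Let $f(x) \in [0,1]^J$ be the feature vector of cell $x$: each continuous
predictor is min–max scaled over the background sample and contributes a
linear and a quadratic feature (the quadratic being the square of the scaled
linear feature, so both live in $[0,1]$); the categorical forest-type layer
contributes one indicator per level observed in the background. The model is
the Gibbs distribution over background cells

$$\mathrm{raw}(x) = \frac{e^{\lambda^\top f(x) - c}}{Z},$$

where $c$ (the *linear predictor normalizer*) is the maximum background
linear predictor, so the exponent is never positive, and $Z$ (the *density
normalizer*) makes raw sum to one over the background. $\lambda$ minimizes
the L1-regularized negative presence log-likelihood

$$-\frac{1}{m}\sum_{i=1}^{m}\lambda^\top f(x_i)
  + \ln\!\!\sum_{x \in \mathrm{bg}} e^{\lambda^\top f(x)}
  + \sum_j \beta_j |\lambda_j|, \qquad
  \beta_j = \beta\, s_j / \sqrt{m},$$

with $s_j$ the background standard deviation of feature $j$ and $m$ the
presence count. The scale-aware $s_j/\sqrt{m}$ form is simpler than the
per-feature-class tuned tables of the original maxent software and is fully
documented here; $\beta$ (default 1) is the single tuning knob. The problem
is convex; we solve it by FISTA (accelerated proximal gradient with
backtracking and adaptive restart) from $\lambda = 0$, stopping when the
relative objective change falls below `tol` (default 1e-8). The optimizer is
deterministic: the seed affects only background sampling, thinning and the
train/test split. Because a complete indicator block sums to one in every
cell, forest-type coefficients are identified only up to an additive shift;
the L1 penalty resolves the shift, and comparisons against generating
coefficients should use a mean-centered truth block (as the synthetic
generator does).

The *entropy* $H = -\sum \mathrm{raw}\ln \mathrm{raw}$ of the fitted
distribution measures how concentrated it is ($H = \ln N$ for the
featureless, uniform model). The logistic output used for mapping is

$$\mathrm{logistic}(x) = \frac{\mathrm{raw}(x)\, e^{H}}
  {1 + \mathrm{raw}(x)\, e^{H}},$$

which maps a cell of "typical" raw value $e^{-H}$ to exactly 0.5 and is
interpreted as probability of presence in $[0,1)$.

Features beyond linear and quadratic (hinge, product, threshold), cumulative
output, and clamping for transfer to new regions are deliberately out of
scope: quadratic response curves keep the candidate models comparable and
the fitted coefficients interpretable.

## Terrain predictors

All layers are 30 m grids co-registered in one planar coordinate system (no
projection handling — inputs are assumed pre-projected):

* **Elevation (E)** — the DEM itself (m).
* **Slope (S)** — Horn's 3×3 third-order finite difference, degrees.
* **Northness/eastness (NS/EW)** — cosine and sine of the downslope azimuth;
  aspect is circular, so it enters as these two components. South-facing
  cells have NS near −1. Flat cells contribute (0, 0).
* **Curvature (C)** — Zevenbergen–Thorne quadratic-surface curvature, scaled
  by 100 (positive = upwardly convex).
* **Distance-to-ridge (R)** — the DEM is smoothed by 10 passes of a 3×3
  focal mean (removing production artifacts), inverted, and run through the
  fill → D8 flow direction → flow accumulation → Strahler stream-order
  chain; "streams" of the inverted surface are crest lines, and R is the
  exact Euclidean distance to them. Slope and curvature also use the
  smoothed DEM; aspect uses the raw DEM, whose fine-scale facets are the
  quantity of interest.
* **Distances to water / major roads / trails (W, MR, TR)** — exact
  Euclidean distance transforms (Felzenszwalb–Huttenlocher) of the
  respective 0/1 source masks. Real-data preprocessing (stream buffering,
  line rasterization) is represented by the mask abstraction.
* **Forest type (FT)** — integer-coded categorical layer.

Numerical conventions worth stating: sink filling uses the iterative
Planchon–Darboux algorithm with an epsilon gradient of $10^{-6}\times$
cellsize, so flats drain deterministically (a pit "raised to spill level" in
fact sits an epsilon above it); D8 ties break toward the smallest direction
code; flow accumulation counts upstream cells excluding the cell itself, so
a cycle in the direction grid (only possible on unfilled input) is an error;
Strahler rather than Shreve ordering is used, with the channel threshold
configurable (default 0.5% of valid cells — scale-free, since no absolute
threshold is canonical); on perfectly flat surfaces the epsilon drainage can
still concentrate flow, so weak spurious channels there are expected rather
than defined away. Edge cells in the 3×3 kernels use mirrored padding, and
nodata neighbours take the centre value.

The collinearity check (`band_statistics()`) computes Pearson correlations
inside circular regions (default radius 1 km) centred on the most and least
rugged windows of the DEM (`ruggedness_centers()`, window standard deviation
of elevation, ties broken row-major).

## Candidate set, AICc, and averaging

The 26-model registry encodes a-priori hypotheses about roost selection
(corridors, foraging needs, pine forest, ridge topography, research bias, a
global model). It is balanced — each of the ten variables appears in exactly
eight models — which makes the weight-sum importance comparable across
variables. One encoding ambiguity deserves note: the foraging hypothesis
names water, trails and major roads, and only with all three does the set
balance, so the registry carries `{W, TR, MR}`; the narrower single-variable
encoding can be loaded through `read_registry()` if wanted.

Occurrences are thinned to one point per stand (reducing spatial
autocorrelation), then split 80/20 once; the identical training and test
sets are reused for every candidate. For each candidate we fit, compute the
log-likelihood of the occurrence points under the raw surface standardized
to sum to one over the whole map, count parameters as the number of nonzero
lambdas (L1 yields exact zeros; the tolerance is configurable), and score

$$\mathrm{AICc} = 2k - 2\ln L + \frac{2k(k+1)}{n - k - 1}.$$

By default $n$ and the log-likelihood use the training points; whether the
original AICc tooling received the training or the full thinned set is not
documented, so this is a flag (`aicc_points`). A model with $k \ge n-1$
cannot be scored at that sample size; it is reported with `NA` and weight 0
rather than silently dropped. Akaike weights, ΔAICc ranks, the strict
`delta < 7` plausible set, and weight-sum importances follow.

AUC (rank-sum concordance against the background, ties half) is reported for
context but never used to rank models — with presence-only data it rewards
overfit discrimination and ignores parsimony.

The final map averages the plausible models' logistic outputs with
renormalized Akaike weights (`--models` style override available), then
classifies with inclusive thresholds: probability ≥ 0.5 suitable, ≥ 0.75
optimal. Suitable area is reported as class ≥ 1, i.e. it includes optimal
cells.

## The synthetic generator

Because the roost coordinates behind the original analysis are not public,
the package ships a generator whose outputs have the statistical structure
the analysis assumes:

* a DEM summing elongated Gaussian ridge crests plus smoothed noise,
  rescaled exactly to 260–2025 m at 30 m cells;
* a 13-code forest mosaic drawn from a multinomial whose logits depend on
  elevation and northness, so pine-type codes concentrate on low,
  south-facing cells but type is not determined by topography;
* streams where flow accumulation exceeds a threshold, and random smooth
  polylines for roads and trails;
* a truth model *in the same functional form the fitter estimates*
  (linear+quadratic on scaled features, indicators for forest type), so
  parameter recovery is well-posed;
* presences drawn without replacement with probability proportional to the
  truth's raw surface, placed at cell centers (sub-cell jitter off, so
  point-in-cell lookups are unambiguous);
* a Voronoi stand partition for thinning.

The default truth coefficients are: forest-type block equal to published
top-model estimates centered to mean zero (centering is the identified
representative; it does not change the generating distribution), northness
−2.1, eastness (0.35, 0.22), elevation (+4, −13) on the scaled feature —
placing the suitability optimum near 530 m, inside the published 260–575 m
response band — and distance-to-ridge −3. The elevation linear term is
positive where the published point estimate is negative: with the −13
quadratic a negative linear term would pin the optimum at the range minimum,
whereas a mid-band optimum both matches the published response band and
keeps the linear term's sign identifiable at realistic sample sizes. The
ridge coefficient is stronger than the published −0.63 so that the
generating distribution genuinely concentrates points near crests (the
sanity property the generator is defined by) instead of being swamped by the
elevation term. Everything is reproducible bit-for-bit from the
configuration: each stage derives its own RNG stream from the run seed via
`stage_seed()`, and no function touches the global RNG state.

What the generator does *not* emulate: the real southern-Appalachian
covariance structure, true hydrography geometry, vegetation-code crosswalks,
GPS error, or detection bias. Passing tests on synthetic scenarios therefore
demonstrate that the machinery is correct and that the design is recoverable
under its own assumptions — not that any particular real landscape would
yield the published map.

## Validation design and problem sizes

The test suite checks the arithmetic of model selection against the
published candidate-set ranking (weights 0.78/0.15/0.05/0.02, combined
top-two weight ≥ 0.93, importances 0.85 for northness and 0.83 for
distance-to-ridge), terrain kernels against independent hand computations on
small printed fixtures, and the fitter against its invariants (background
normalization to 1e-9, entropy bounds, convexity via multi-start agreement).

Two simulation studies probe statistical behaviour, both at 20 seeded
replicates on the default 200×200 grid:

* **Sign recovery** — 500 presences, light regularization (β = 0.01): every
  truth coefficient with $|\lambda| \ge 1$ must keep its sign in ≥ 95% of
  replicates.
* **Rank recovery** — 300 presences thinned over a 200-stand partition
  (≈ 115 points after thinning): the generating candidate model must rank
  1st or 2nd by AICc in ≥ 80% of replicates. The stand partition is finer
  here than the 54-stand default because whole-extent Voronoi stands are far
  larger than real management stands; thinning 76 points over 54 such
  polygons leaves only ~33 — too few for AICc to separate 26 candidates
  reliably, which is an information limit of that configuration rather than
  a property of the estimator, and at the default scale the generating model
  still ranks top-2 in roughly half the replicates.

These sizes (200×200 cells, 10,000 background cells, 20 replicates) are the
package's chosen simulation design: large enough for the asymptotics to
show, small enough to run on a laptop in minutes.

## Known limitations

* Single-flow-direction (D8) routing only; no D-infinity or multiple-flow
  alternatives.
* No projection/datum handling and no cartographic output.
* The regularization schedule is deliberately simpler than the original
  maxent software's tuned feature-class tables, so fitted lambdas are
  comparable between the two only in sign and rough magnitude.
* `aicc` treats occurrence points as independent given the surface; residual
  spatial autocorrelation beyond stand-level thinning is not modelled.
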