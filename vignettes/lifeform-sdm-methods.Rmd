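---
title: "Life-form-stratified suitability modeling with a human-influence factor: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-form-stratified suitability modeling with a human-influence factor: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Habitat-suitability models (SDMs) relate species occurrence records to
gridded environmental layers and predict, for every cell of a study region,
the probability that the species finds suitable conditions there. Two
methodological questions drive this package:

1. **Physiology-aware stratification.** Plant groups with contrasting life
   forms — soil-rooted *terrestrial* plants, canopy-dwelling *epiphytes*,
   and fungus-dependent *mycoheterotrophs* — have distinct environmental
   requirements. Pooling all records into one model blurs those
   requirements; fitting one model per life form and fusing the resulting
   maps can recover them. The package lets you run both strategies and
   compare them with paired tests.
2. **Quantified human influence.** Human pressure is rarely entered into
   plant SDMs as a predictor. The package builds a composite
   human-influence (HI) raster from five 0–10 indexes — population density,
   grazing density, road access, night-time light, and land use — and lets
   you rerun every model with and without it.

Everything runs on a shared 1-km equal-area grid, so cell counts are areas
in km² and county-level zonal statistics are plain tallies.

# The HI factor

Each index maps a raw anthropogenic layer onto a bounded score:

* **Population** (people/km²): densities above 1000 score 10; below the cap
  the score is the human-footprint logarithmic rule
  $\min(10,\; 3.333\,\log_{10}(d + 1))$, which meets the cap rule
  continuously at $d = 1000$.
* **Grazing**: county livestock is converted to sheep equivalents (1 cattle
  head = 5 sheep), divided by county area to give $x_i$, and each cell of
  county $i$ scores $\mathrm{clamp}\!\left(\frac{\log x_i}{\log x_{\max}}
  \times 10,\; 0,\; 10\right)$. The log base cancels in the ratio; the
  county attaining $x_{\max}$ scores exactly 10. The formula degenerates
  when $x_{\max} \le 1$ (the score would invert), so that case is an error
  asking for rescaled units rather than a silent wrong answer.
* **Road access**: per road class, the distance from the cell center to the
  nearest road is binned into half-open bins
  $[0, 90), [90, 500), [500, 1000), [1000, 3000)$ m with class-specific
  scores (national highways 10/8/6/4, railways and provincial highways
  8/6/4/2, county roads 6/4/2/0, village roads 4/2/1/0); beyond 3000 m a
  class contributes 0. A cell's score is the **maximum** over classes —
  worst-case accessibility. Boundary distances fall in the farther bin.
* **Night light**: radiance cells are ranked and assigned decile bins 1–10
  (`ceiling(rank * 10 / n)` with ties taking their lowest member's rank, so
  tied values land in the lower bin; a constant raster scores 1
  everywhere). Zeros participate in the ranking.
* **Land use**: a point lookup — construction 10, arable 7, forest 3,
  irrigation 3, grassland 1, anything else (snow, ice, water) 0.

The HI layer is the **unweighted sum** of the five scores, range
$[1, 50]$ (night light's floor is 1). It is deliberately not rescaled:
"normalized" is read as "each index already on its 0–10 scale", and users
wanting a 0–1 HI can divide by 50. Whether the night-light floor of 1
(versus 0 elsewhere) is intentional in the original scheme is unknowable
from the published rules; it is implemented as printed.

# Occurrence preparation

* **Life-form classification** partitions records into `t`, `e`, `m` sets
  and keeps the pooled `all` set; counts are conserved exactly.
* **Thinning** enforces the 1-km spatial-autocorrelation limit as
  one-record-per-grid-cell deduplication (the first record in each cell is
  kept). At 1-km resolution this is equivalent to 1-km distance thinning
  and, unlike pairwise thinning, is deterministic and idempotent. Thinning
  is applied per dataset after pooling, so the `all` set is thinned
  independently of its components.
* **Pseudo-absences**: 2000 cells per set, drawn uniformly without
  replacement from valid non-presence cells, three independent sets per
  dataset (each dataset excludes only its *own* presences).
* **Splits**: 70/30 train/test, five repetitions per pseudo-absence set,
  stratified by class so all 15 runs per strategy see the same class
  balance.
* **Collinearity**: greedy filtering of continuous predictors at
  $|r| \ge 0.7$ (the member of the worst pair with the larger mean absolute
  correlation is dropped). Categorical layers are exempt.

# The three algorithms

All three emit suitability in $[0, 1]$ through one predict contract, from a
common feature pipeline: continuous predictors z-scored with *training*
statistics, categorical predictors one-hot encoded over their training
registry.

* **GLM** — binomial-logit fit on the quadratic feature class (each
  continuous main effect plus its square — the default polynomial logit of
  the usual SDM platforms) with interaction level 1: all pairwise products
  of main-effect columns (products of two indicators of the same
  categorical are structurally zero and excluded). The fit is damped
  Newton/IRLS on the mean log-likelihood with a tiny ridge ($10^{-6}$) so
  quasi-separable runs stay finite; convergence is declared at gradient
  norm $10^{-8}$, and failing to converge within 500 iterations is an
  error, not a warning.
* **RF** — a seeded 1000-tree probability forest (class-frequency
  averaging; `ranger` with its probability-forest node size of 10).
  Suitability is the forest's presence probability. With fully grown trees
  this coincides in expectation with the per-tree vote fraction; the
  probability forest is the standard smooth-suitability convention.
* **MaxEnt-style** — the presence–background maximum-entropy model fit in
  its equivalent penalized logistic form: presences against the dataset's
  pseudo-absence cells as background, linear + quadratic features, an L1
  penalty of total weight 1 (passed to `glmnet` as `lambda = 1/n`), and
  class-balanced weights so a zero-signal fit predicts a flat ~0.5. This is
  an approximation of, not a port of, the original MaxEnt software: hinge
  and threshold features are deliberately out of scope, so exact numeric
  parity with MaxEnt fits is neither attainable nor claimed.

# Evaluation

AUC is the rank-based (Mann–Whitney) probability that a random presence
outscores a random absence, with half-credit for ties. TSS is
$\text{sensitivity} + \text{specificity} - 1$; Kappa is chance-corrected
agreement with chance from the marginal products. TSS and Kappa are
reported at the **metric-maximizing threshold** (scanning every distinct
score, ties to the lowest threshold; the fixed-0.5 values are logged
alongside). Strategy comparisons are **paired** two-sided t-tests over the
15 shared (pseudo-absence set, split) run labels, one test per metric, at
$\alpha = 0.05$, with no multiple-testing correction — this mirrors the
presentation convention of the comparison figures it reproduces, and the
absence of correction is a deliberate, logged caveat.

# Maps, change analysis, and the double ranking

Committee-mean suitability (mean over the 15 runs of a strategy) is
binarized at 0.5 — *strictly* greater than, so a cell at exactly 0.5 is
unsuitable. The three life-form maps are fused by cell-wise OR into a
"total" layer and compared with the pooled "all" map as a symmetric
difference; changed areas are reported in km² and as a percentage of the
study area (unmasked cells × cell area).

County prioritization uses the double ranking: (i) the *sequential* screen
keeps the top 30% of counties by suitable area (`ceiling(0.3 n)`, ties
broken by county id; the fraction applies to all counties in the table,
including zero-area ones); (ii) the *area-weight* screen keeps the smallest
descending-area prefix accumulating 50% of the total suitable area. The two
screens are intersected per strategy, and the across-strategy intersection
is the consensus — counties at the forefront regardless of modeling
strategy. Both marginal sets are also reported so other join rules can be
applied downstream.

# The synthetic study system

The generator emulates the statistical structure the analysis assumes — it
is a synthetic twin of a mountainous ~1-km study region, not of any real
place:

* Continuous predictors are smoothed Gaussian random fields (white noise
  blurred with a separable Gaussian kernel of 10 cells by default) built
  from shared latent fields — temperature, precipitation, relief,
  development — with loadings capped so no predictor pair exceeds
  $|r| \approx 0.5$: realistic coupling that still survives the
  $|r| < 0.7$ filter, keeping the assembled stack at its full 14 predictors
  (5 bioclimatic, vegetation, elevation, slope, aspect, 4 soil attributes,
  HI).
* Slope and aspect derive from elevation by central differences.
  Vegetation and land use are categorical quantile cuts of latent fields;
  population and night light both increase with the development latent, so
  they correlate with each other and with construction land use.
* Counties are a rectangular partition with randomized breakpoints (a
  partition is guaranteed, so zonal areas are additive by construction);
  livestock tables are log-normal across counties. Roads are random
  polylines per class.
* Occurrences follow a logistic niche:
  $p = \operatorname{logit}^{-1}\!\big(\beta_0 + \sum_k \beta_k z_k +
  \varepsilon\big)$ over z-scored layers (categorical layers pass through a
  class-preference score first), sampled by uniform proposal and Bernoulli
  acceptance, placed at cell centers.

**Niche presets.** No published effect sizes exist for life-form/
environment relationships, so the presets are the package's stated
defaults, chosen once: sharp niches whose suitable regions occupy a few
percent of the landscape — a strong-signal regime in which all strategies
evaluate as adequate (AUC > 0.8, best-threshold TSS/Kappa > 0.4), the
regime reported for the real systems this emulates. The terrestrial niche is broad (temperature, precipitation,
elevation, soil; 2000 points), the epiphytic niche is precipitation- and
warm-season-driven (80 points), and the mycoheterotrophic niche is
vegetation- and cool-summer-driven (200 points) — the 2000/200/80 imbalance
mirrors the order-of-magnitude imbalance of real orchid record sets.

**What passing tests do and do not show.** The synthetic twin has smooth
fields, uniform sampling effort, exact life-form labels, and no spatial
sampling bias; real occurrence data have none of these luxuries. Passing
the directional tests shows the *pipeline* reproduces the qualitative
phenomena under its own assumptions — not that those phenomena must appear
in any real data set.

# Numerical and design choices

* Grid indexing is row-major from the top-left origin; points map to cells
  by half-open intervals; a cell belongs to the county containing its
  center (ties to the lowest county id). Nodata propagates through every
  operation.
* Rasters are stored as plain-text Esri ASCII grids at full double
  precision (`%.17g`), with a JSON sidecar for the CRS identifier, giving
  bit-exact round trips; vectors are GeoJSON. No CRS is ever guessed: the
  user (or the generator) must name the equal-area projection, and CRS or
  grid mismatches are errors, never silent reprojection or resampling.
* The committee map is the mean over a strategy's runs (the aggregation
  rule is otherwise unstated in the literature this follows); binarization
  happens after averaging.
* Directional map comparisons (pooled versus fused areas) use RF committee
  maps: the probability forest shrinks rare-class probabilities toward the
  prevalence, which is the mechanism that makes small life-form datasets
  produce small maps at the 0.5 threshold. The direction is
  algorithm-dependent in the synthetic twin — interaction-only GLM features
  (no squares, per the stated feature contract) and the balanced-weight
  maxent can invert it.
* Master-seed fan-out: every stage derives its seed as an FNV-style hash of
  the stage name mixed with the master seed, so stages are independently
  reproducible and never collide.

**Problem sizes.** The shipped tests exercise the full default system —
a 200×200-cell landscape, 4 datasets × 3 algorithms × 2 HI conditions ×
3 pseudo-absence sets × 5 splits (360 runs) — once, plus five replicate
worlds (one run each) for the directional properties and small purpose-built
grids for the unit oracles. These sizes are the package's reference
configuration for simulation studies.

# Known limitations

* The maxent-style model is a principled stand-in, not MaxEnt; hinge
  features, clamping and the cloglog output are absent.
* Pseudo-absence sampling is uniform only; target-group or
  environmentally stratified background designs are out of scope.
* No spatially blocked cross-validation: the 70/30 splits are random, so
  reported skill on strongly autocorrelated landscapes is optimistic in the
  way random-split SDM evaluations usually are.
* County polygons are assumed non-overlapping; overlaps are resolved by
  county id, not by area of intersection.
* The paired t-tests are applied per metric without multiple-testing
  correction, as in the figures they mirror.
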