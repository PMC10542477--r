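# hisdm

Life-form-stratified species distribution models (SDMs) with a quantified
human-influence factor, on a shared 1-km equal-area grid.

## The problem

Species distribution models relate occurrence records to gridded
environmental predictors and map habitat suitability. For groups whose
members differ sharply in growth habit — terrestrial, epiphytic and
mycoheterotrophic plants such as orchids — pooling all records into one
model blurs the distinct environmental requirements of each life form, and
human pressure is usually left out of the predictor set entirely. `hisdm`
is a tested pipeline for studying both effects:

* a composite **human-influence (HI) raster**, the equal-weight sum of five
  0–10 indexes — population density (capped logarithmic rule
  `min(10, 3.333 log10(d + 1))`, 10 above 1000 people/km²), grazing density
  (`log(x_i) / log(x_max) × 10` over county sheep-equivalents, 1 cattle = 5
  sheep), road access (class × distance-bin scores, maximum over classes),
  night-light deciles (1–10), and land-use points (10/7/3/3/1/0);
* **occurrence preparation**: life-form classification into the `all`, `t`,
  `e`, `m` datasets, one-record-per-cell spatial thinning, 3 × 2000 uniform
  pseudo-absence sets per dataset, stratified 70/30 splits × 5 repeats, and
  greedy collinearity filtering at |r| ≥ 0.7;
* three **suitability algorithms** behind one predict contract — a
  stepwise-AIC quadratic logistic GLM with pairwise interactions, a
  1000-tree probability random forest, and a presence–background
  maxent-style weighted lasso (linear + quadratic features);
* self-implemented **evaluation**: rank-based AUC, best-threshold TSS and
  Kappa, and paired t-tests comparing modeling strategies (stratified vs
  pooled; HI on vs off);
* **map analysis**: committee-mean suitability, strict binarization at 0.5,
  OR-fusion of the life-form maps into a total layer, symmetric-difference
  change maps, and county-level zonal areas;
* the **double ranking** of critical counties: top 30% by suitable-area
  rank intersected with the smallest top-area set holding 50% of the total
  suitable area, intersected across strategies into a consensus.

A seeded synthetic-landscape generator (smoothed Gaussian random fields,
categorical vegetation/land use, roads, rectangular county partitions,
livestock tables, and logistic life-form niches) provides a fully
self-contained study system, so the entire pipeline runs and is tested
without any external data. See `vignettes/lifeform-sdm-methods.Rmd` for the
model details and design decisions.

## Worked example

A reduced run (80 × 80-cell landscape, GLM + RF, 2 pseudo-absence sets × 3
splits; about two minutes on one CPU):

```r
library(hisdm)

niches <- list(
  t = niche_params("terrestrial", c(bio01 = 2, bio12 = 1.6, elevation = -1.6),
                   intercept = -5, n_points = 400, sampling_noise = 0.25),
  e = niche_params("epiphytic", c(bio13 = 4, bio15 = 2.5, bio10 = 2.5),
                   intercept = -9, n_points = 60, sampling_noise = 0.25),
  m = niche_params("mycoheterotrophic", c(vegetation = 3, bio10 = -2.5),
                   intercept = -6.5, n_points = 100, sampling_noise = 0.25))
cfg <- run_config(
  landscape = landscape_params(seed = 7, n_rows = 80, n_cols = 80,
                               n_counties = 16, spatial_corr_length = 8),
  niches = niches, n_pa = 500, n_pa_sets = 2, n_repeats = 3,
  algorithms = c("glm", "rf"), hi = c(TRUE, FALSE), seed = 7)
res <- run_pipeline(cfg)

aggregate(res$metrics[, c("auc", "tss", "kappa")],
          by = list(strategy = res$metrics$strategy), FUN = mean)
```

```
   strategy  auc  tss kappa
      G-all 0.81 0.50  0.50
        G-e 0.85 0.66  0.43
        G-m 0.92 0.75  0.64
        G-t 0.89 0.67  0.65
      R-all 0.82 0.51  0.51
        R-e 0.91 0.72  0.56
        R-m 0.90 0.74  0.68
        R-t 0.88 0.66  0.63
  ...            (plus the -noHI half)
```

Every strategy (`G`/`R` = GLM / random forest × dataset) evaluates above
AUC 0.8 here, and the life-form models outscore the pooled `all` model.
The paired comparisons quantify that:

```r
subset(res$comparisons, family == "classification_vs_all" & metric == "auc",
       select = c(group_a, group_b, mean_diff, p_value, significant))
```

```
 group_a group_b mean_diff p_value significant
     G-t   G-all     0.076 0.00572        TRUE
     G-e   G-all     0.042 0.06667       FALSE
     G-m   G-all     0.108 0.00020        TRUE
     R-t   R-all     0.067 0.00265        TRUE
     R-e   R-all     0.092 0.00050        TRUE
     R-m   R-all     0.086 0.00051        TRUE
 ...
```

so stratifying by life form raises held-out AUC by 0.04–0.11, significantly
in most strategies. Downstream products follow the same object:

```r
res$changes[["G-all"]]$changed_area_km2   # pooled-vs-fused change map, km2
res$rankings$all$consensus                # double-ranking consensus counties
```

```
changed area (G): 710 km2 (11.09% of the study area)
consensus critical counties (all-data): C04, C05, C06, C03
```

The change map is the symmetric difference between the pooled `all`-data
binary map and the OR-fusion of the three life-form maps; the consensus
counties are those passing both ranking screens under every modeling
strategy.

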