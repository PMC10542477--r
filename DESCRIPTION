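Package: hisdm
Title: Life-Form-Stratified Species Distribution Models with a Human-Influence Factor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for habitat-suitability modelling of plant
    groups with contrasting life forms (terrestrial, epiphytic,
    mycoheterotrophic) on a shared 1-km equal-area grid. Provides a composite
    human-influence (HI) raster score built from five 0-10 indexes (population
    density, grazing density, road access, night-time light, land use);
    occurrence preparation (life-form classification, grid-cell thinning,
    pseudo-absence sampling, stratified train/test splits, collinearity
    filtering); three suitability algorithms (penalized logistic GLM with
    pairwise interactions, 1000-tree random forest, and a presence-background
    maximum-entropy-style weighted lasso); self-contained AUC/TSS/Kappa
    evaluation with paired strategy comparisons; suitability-map binarization,
    life-form fusion and change analysis with county-level zonal areas; and a
    double-ranking selection of critical conservation counties. A seeded
    synthetic-landscape generator supplies gridded predictors, road networks,
    county polygons, livestock tables and life-form-specific occurrences for
    testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
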