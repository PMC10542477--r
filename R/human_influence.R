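#' Bounded human-influence score layer
#'
#' Each of the five human-influence indexes lives on a 0-10 score scale
#' (night light on 1-10); a `score_layer` couples the scored raster with its
#' bounds and index name and validates them.
#'
#' @param raster A `raster_layer` of scores.
#' @param index_name One of `"population"`, `"grazing"`, `"access"`,
#'   `"nightlight"`, `"landuse"`.
#' @param score_min,score_max Score bounds.
#' @return An object of class `score_layer`.
#' @export
score_layer <- function(raster, index_name,
                        score_min = if (index_name == "nightlight") 1 else 0,
                        score_max = 10) {
  index_name <- match.arg(index_name,
                          c("population", "grazing", "access", "nightlight", "landuse"))
  v <- raster$values[raster$mask]
  if (length(v) && (min(v) < score_min - 1e-9 || max(v) > score_max + 1e-9)) {
    stop(sprintf("%s scores outside [%g, %g]", index_name, score_min, score_max))
  }
  structure(list(raster = raster, index_name = index_name,
                 score_min = score_min, score_max = score_max),
            class = "score_layer")
}

#' Human-influence configuration
#'
#' @param population_cap Population density (people/km2) above which the
#'   population score saturates at 10.
#' @param landuse_points Named score map for land-use classes. The default
#'   implements the published point scheme: construction 10, arable 7,
#'   forest and irrigation 3, grassland 1, everything else 0.
#' @param nightlight_bins Number of quantile bins for the night-light score.
#' @return A list of class `hi_config`.
#' @export
hi_config <- function(population_cap = 1000,
                      landuse_points = c(construction = 10, arable = 7,
                                         forest = 3, irrigation = 3,
                                         grassland = 1, other = 0),
                      nightlight_bins = 10L) {
  stopifnot(population_cap > 0, nightlight_bins >= 2,
            all(landuse_points %in% c(0, 1, 3, 7, 10)))
  structure(list(population_cap = population_cap,
                 landuse_points = landuse_points,
                 nightlight_bins = as.integer(nightlight_bins)),
            class = "hi_config")
}

#' Road-access scoring table
#'
#' Scores by road class and distance bin. Bins are half-open:
#' `[0, 90)`, `[90, 500)`, `[500, 1000)`, `[1000, 3000)` metres, and any cell
#' 3000 m or farther from a class scores 0 for that class. Scores must be
#' non-increasing with distance and lie in `[0, 10]`.
#'
#' @param scores Data frame with columns `road_class`, `d0_90`, `d90_500`,
#'   `d500_1000`, `d1000_3000`.
#' @return A data frame of class `access_table`.
#' @export
access_table <- function(scores) {
  cols <- c("road_class", "d0_90", "d90_500", "d500_1000", "d1000_3000")
  stopifnot(all(cols %in% names(scores)))
  m <- as.matrix(scores[, cols[-1]])
  stopifnot(all(m >= 0), all(m <= 10))
  if (any(t(apply(m, 1, diff)) > 0)) {
    stop("access scores must be non-increasing with distance within each class")
  }
  structure(scores[, cols], class = c("access_table", "data.frame"))
}

#' Default road-access scores
#'
#' Five road classes scored over four distance bins: railways and
#' provincial-level highways 8/6/4/2, national-level highways 10/8/6/4,
#' county-level highways 6/4/2/0 and village-level highways 4/2/1/0.
#' @return An `access_table`.
#' @export
access_table_default <- function() {
  access_table(data.frame(
    road_class = c("railway", "national_highway", "provincial_highway",
                   "county_highway", "village_highway"),
    d0_90      = c(8, 10, 8, 6, 4),
    d90_500    = c(6,  8, 6, 4, 2),
    d500_1000  = c(4,  6, 4, 2, 1),
    d1000_3000 = c(2,  4, 2, 0, 0),
    stringsAsFactors = FALSE))
}

#' Population-density score (0-10)
#'
#' Densities above the cap (default 1000 people/km2) score 10; below it the
#' score is the human-footprint logarithmic rule
#' `min(10, 3.333 * log10(density + 1))`, which is continuous with the cap
#' rule at 1000.
#'
#' @param density A `raster_layer` of population density (people/km2, >= 0).
#' @param cfg An [hi_config()].
#' @return A `score_layer`.
#' @export
score_population <- function(density, cfg = hi_config()) {
  v <- raster_values_vec(density); m <- raster_mask_vec(density)
  if (any(v[m] < 0)) stop("population density must be non-negative")
  s <- pmin(10, 3.333 * log10(v + 1))
  s[v > cfg$population_cap] <- 10
  s[!m] <- NA_real_
  score_layer(raster_layer(density$grid, s, matrix(m, density$grid$n_rows,
                                                   density$grid$n_cols, byrow = TRUE)),
              "population")
}

#' Grazing-density score (0-10)
#'
#' Converts county livestock to sheep equivalents (one cattle head counts as
#' five sheep), forms the density `x_i = (5 * cattle + sheep) / area_km2`,
#' and scores every cell of county *i* as
#' `clamp(log(x_i) / log(x_max) * 10, 0, 10)` where `x_max` is the largest
#' county density. The log base cancels in the ratio (natural log used).
#' The county attaining `x_max` scores exactly 10.
#'
#' @param records Data frame with `county_id`, `cattle`, `sheep` (head
#'   counts).
#' @param counties A `county_table` (supplies polygon membership and areas).
#' @param grid A `grid_spec`.
#' @param assignment Optional precomputed [county_assignment()].
#' @return A `score_layer`; cells outside every county are masked.
#' @export
score_grazing <- function(records, counties, grid, assignment = NULL) {
  stopifnot(nrow(records) >= 1,
            all(c("county_id", "cattle", "sheep") %in% names(records)))
  i <- match(records$county_id, counties$county_id)
  if (anyNA(i)) stop("livestock records name unknown counties: ",
                     paste(records$county_id[is.na(i)], collapse = ", "))
  x <- (5 * records$cattle + records$sheep) / counties$area_km2[i]
  if (all(x == 0)) stop("all sheep-equivalent densities are zero; grazing score undefined")
  x_max <- max(x)
  if (x_max <= 1) {
    stop("maximum sheep-equivalent density <= 1 per km2; log-ratio scoring ",
         "degenerates. Rescale the density units (e.g. head per km2).")
  }
  sc <- pmin(10, pmax(0, log(x) / log(x_max) * 10))
  sc[x <= 0] <- 0
  if (is.null(assignment)) assignment <- county_assignment(grid, counties)
  by_row <- rep(NA_real_, nrow(counties))
  by_row[i] <- sc
  vals <- by_row[assignment]
  score_layer(raster_layer(grid, vals, matrix(!is.na(vals), grid$n_rows,
                                              grid$n_cols, byrow = TRUE)),
              "grazing")
}

#' Sheep-equivalent county densities
#'
#' @inheritParams score_grazing
#' @return Data frame with `county_id`, `x_i` (sheep equivalents per km2).
#' @export
sheep_equivalent_density <- function(records, counties) {
  i <- match(records$county_id, counties$county_id)
  data.frame(county_id = records$county_id,
             x_i = (5 * records$cattle + records$sheep) / counties$area_km2[i])
}

#' Road-access score (0-10)
#'
#' For each road class the cell's distance to the nearest road of that class
#' is binned against the access table; the cell score is the maximum over
#' classes (worst-case accessibility).
#'
#' @param grid A `grid_spec`.
#' @param roads A `feature_set` of lines with a `road_class` attribute.
#' @param table An [access_table()]; defaults to [access_table_default()].
#' @return A `score_layer`.
#' @export
score_access <- function(grid, roads, table = access_table_default()) {
  stopifnot(inherits(roads, "feature_set"))
  cls <- roads$attributes$road_class
  if (is.null(cls)) stop("roads need a 'road_class' attribute")
  unknown <- setdiff(unique(cls), table$road_class)
  if (length(unknown)) stop("unknown road class: ", paste(unknown, collapse = ", "))
  score <- rep(0, n_cells(grid))
  for (k in unique(cls)) {
    sub <- feature_set(roads$geoms[cls == k], crs_id = roads$crs_id)
    d <- raster_values_vec(distance_to_features(grid, sub))
    row <- as.numeric(table[table$road_class == k, c("d0_90", "d90_500",
                                                     "d500_1000", "d1000_3000")])
    s <- rep(0, length(d))
    s[d < 3000] <- row[4]
    s[d < 1000] <- row[3]
    s[d < 500] <- row[2]
    s[d < 90] <- row[1]
    score <- pmax(score, s)
  }
  score_layer(raster_layer(grid, score), "access")
}

#' Night-light score (1-10) by quantile grading
#'
#' Unmasked cells are ranked (ties take the rank of their lowest member, so
#' tied values always map to the lower bin) and assigned decile bins 1..10:
#' `bin = ceiling(rank * bins / n)`. A constant raster therefore scores 1
#' everywhere, and with all-distinct values the minimum scores 1 and the
#' maximum 10.
#'
#' @param radiance A `raster_layer` of non-negative radiance.
#' @param cfg An [hi_config()].
#' @return A `score_layer`.
#' @export
score_nightlight <- function(radiance, cfg = hi_config()) {
  v <- raster_values_vec(radiance); m <- raster_mask_vec(radiance)
  if (any(v[m] < 0)) stop("radiance must be non-negative")
  n <- sum(m)
  if (n < cfg$nightlight_bins) {
    stop(sprintf("only %d unmasked cells for %d quantile bins", n, cfg$nightlight_bins))
  }
  r <- rank(v[m], ties.method = "min")
  bin <- pmin(cfg$nightlight_bins, ceiling(r * cfg$nightlight_bins / n))
  bin <- pmax(1, bin)
  s <- rep(NA_real_, length(v))
  s[m] <- bin
  score_layer(raster_layer(radiance$grid, s,
                           matrix(m, radiance$grid$n_rows, radiance$grid$n_cols,
                                  byrow = TRUE)),
              "nightlight")
}

#' Land-use score (0-10)
#'
#' Point lookup per land-use class: construction 10, arable 7, forest and
#' irrigation 3, grassland 1, other (e.g. permanent snow and ice) 0.
#'
#' @param classes A categorical `raster_layer` of integer class codes with a
#'   `levels` attribute (or pass `levels` explicitly).
#' @param cfg An [hi_config()] supplying the score map.
#' @param levels Character vector mapping codes to class names.
#' @return A `score_layer`.
#' @export
score_landuse <- function(classes, cfg = hi_config(),
                          levels = attr(classes, "levels")) {
  if (is.null(levels)) stop("land-use raster needs a class-level registry")
  v <- raster_values_vec(classes); m <- raster_mask_vec(classes)
  nm <- levels[v[m]]
  unmapped <- setdiff(unique(nm), names(cfg$landuse_points))
  if (length(unmapped)) stop("land-use class without a score: ",
                             paste(unmapped, collapse = ", "))
  s <- rep(NA_real_, length(v))
  s[m] <- unname(cfg$landuse_points[nm])
  score_layer(raster_layer(classes$grid, s,
                           matrix(m, classes$grid$n_rows, classes$grid$n_cols,
                                  byrow = TRUE)),
              "landuse")
}

#' Compose the human-influence (HI) layer
#'
#' Cell-wise unweighted sum of the five index score layers, each already on
#' its 0-10 (night light 1-10) scale; the theoretical range is therefore
#' `[1, 50]`. The output mask is the intersection of the input masks. The sum
#' is deliberately not rescaled; users wanting a 0-1 HI can divide by 50.
#'
#' @param population,grazing,access,nightlight,landuse `score_layer`s with
#'   matching index names on one shared grid.
#' @return A `raster_layer`.
#' @export
compose_hi <- function(population, grazing, access, nightlight, landuse) {
  layers <- list(population = population, grazing = grazing, access = access,
                 nightlight = nightlight, landuse = landuse)
  g <- layers[[1]]$raster$grid
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "score_layer") || l$index_name != nm) {
      stop("compose_hi() needs the five index score layers, in name: ", nm)
    }
    if (!same_grid(l$raster$grid, g)) stop("score layers on different grids")
  }
  vals <- Reduce(`+`, lapply(layers, function(l) raster_values_vec(l$raster)))
  mask <- Reduce(`&`, lapply(layers, function(l) raster_mask_vec(l$raster)))
  vals[!mask] <- NA_real_
  raster_layer(g, vals, matrix(mask, g$n_rows, g$n_cols, byrow = TRUE))
}

#' Compute the HI layer for a synthetic landscape
#'
#' Convenience wrapper running all five index scores on a `landscape` and
#' composing them.
#'
#' @param landscape A `landscape` from [generate_landscape()].
#' @param cfg An [hi_config()].
#' @param table An [access_table()].
#' @return List with the five `score_layer`s and the composed `hi` raster.
#' @export
compute_hi <- function(landscape, cfg = hi_config(), table = access_table_default()) {
  assignment <- county_assignment(landscape$grid, landscape$counties)
  pop <- score_population(landscape$human$population, cfg)
  grz <- score_grazing(landscape$livestock, landscape$counties, landscape$grid,
                       assignment = assignment)
  acc <- score_access(landscape$grid, landscape$human$roads, table)
  ntl <- score_nightlight(landscape$human$nightlight, cfg)
  lnd <- score_landuse(landscape$human$landuse, cfg)
  list(population = pop, grazing = grz, access = acc, nightlight = ntl,
       landuse = lnd, hi = compose_hi(pop, grz, acc, ntl, lnd))
}

#' Assemble the modeling predictor stack
#'
#' Binds the environmental layers with the composed HI layer into the full
#' stack used for modeling: 5 bioclimatic layers, vegetation, elevation,
#' slope, aspect, 4 soil attributes and HI — 14 predictors. With
#' `hi = NULL` the stack has 13 (the HI-off condition).
#'
#' @param landscape A `landscape`.
#' @param hi The composed HI `raster_layer`, or `NULL` to omit it.
#' @return A `predictor_stack`.
#' @export
assemble_stack <- function(landscape, hi = NULL) {
  layers <- landscape$env$layers
  if (!is.null(hi)) layers$hi <- hi
  predictor_stack(layers, categorical = landscape$env$categorical)
}
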