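#' Parameters of the synthetic study system
#'
#' The generator emulates a mountainous ~1-km gridded study region: smoothed
#' Gaussian random fields for climate/soil, an elevation field with derived
#' slope and aspect, a categorical vegetation map, correlated human layers
#' (population density, night-time light, land use), random road networks by
#' class, an administrative partition into counties, and county livestock
#' tables. Every draw is fixed by `seed`.
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_rows,n_cols Grid dimensions (default 200 x 200 cells).
#' @param cell_size Cell edge (m), default 1000.
#' @param crs_id Identifier of the synthetic equal-area CRS.
#' @param spatial_corr_length Gaussian smoothing length of the random fields,
#'   in cells (must be >= 1).
#' @param n_counties Number of counties in the administrative partition.
#' @param n_roads_per_class Named integer vector of road counts per class.
#' @return A list of class `landscape_params`.
#' @export
landscape_params <- function(seed = 1L, n_rows = 200L, n_cols = 200L,
                             cell_size = 1000, crs_id = "synthetic:laea",
                             spatial_corr_length = 10,
                             n_counties = 25L,
                             n_roads_per_class = c(railway = 1L,
                                                   national_highway = 1L,
                                                   provincial_highway = 2L,
                                                   county_highway = 3L,
                                                   village_highway = 4L)) {
  stopifnot(spatial_corr_length >= 1, n_counties >= 1)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), cell_size = cell_size,
                 crs_id = crs_id, spatial_corr_length = spatial_corr_length,
                 n_counties = as.integer(n_counties),
                 n_roads_per_class = n_roads_per_class),
            class = "landscape_params")
}

#' Stack of named predictor layers on one grid
#'
#' @param layers Named list of `raster_layer`s sharing one grid.
#' @param categorical Named list mapping categorical layer names to their
#'   level registries (character vectors indexed by integer code).
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, categorical = list()) {
  stopifnot(length(layers) > 0, !is.null(names(layers)), !anyDuplicated(names(layers)))
  g <- layers[[1]]$grid
  for (l in layers) stopifnot(same_grid(l$grid, g))
  stopifnot(all(names(categorical) %in% names(layers)))
  structure(list(grid = g, layers = layers, categorical = categorical),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers (%s categorical) on %d x %d grid\n",
              length(x$layers), length(x$categorical), x$grid$n_rows, x$grid$n_cols))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

stack_mask <- function(stack) {
  m <- Reduce(`&`, lapply(stack$layers, raster_mask_vec))
  m
}

## Smoothed standard Gaussian random field: white noise blurred with a
## separable Gaussian kernel of scale L cells, then standardized over cells.
.gaussian_field <- function(n_rows, n_cols, L) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  sm <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    w <- exp(-0.5 * (d / L)^2)
    w / rowSums(w)
  }
  f <- sm(n_rows) %*% z %*% t(sm(n_cols))
  (f - mean(f)) / stats::sd(f)
}

.zscore <- function(x) (x - mean(x)) / stats::sd(x)

#' Generate the full synthetic study system
#'
#' Continuous predictors are built from shared latent fields (a temperature
#' latent, a precipitation latent, elevation, development) plus layer-specific
#' fields, with loadings chosen so that no predictor pair exceeds |r| ~ 0.5 —
#' strong enough to be realistic, weak enough that the default stack survives
#' the |r| < 0.7 collinearity filter intact. Population and night light both
#' increase with the development latent (hence are positively correlated with
#' each other and with construction land use). Counties partition the grid
#' into rectangles with randomized breakpoints. Elevation yields slope and
#' aspect by central finite differences.
#'
#' @param params A [landscape_params()] object.
#' @return A list of class `landscape` with elements `grid`, `env` (a
#'   13-layer `predictor_stack`), `human` (population/nightlight/landuse
#'   rasters and the `roads` feature set), `counties` (a `county_table`),
#'   `livestock` (a county livestock table) and `params`.
#' @export
generate_landscape <- function(params = landscape_params()) {
  nr <- params$n_rows; nc <- params$n_cols
  if (params$n_counties > nr * nc) stop("more counties than grid cells")
  set.seed(params$seed)
  grid <- grid_spec(origin_x = 0, origin_y = nr * params$cell_size,
                    cell_size = params$cell_size, n_rows = nr, n_cols = nc,
                    crs_id = params$crs_id)
  L <- params$spatial_corr_length
  gf <- function() .gaussian_field(nr, nc, L)

  E <- gf()   # relief latent
  C <- gf()   # regional temperature latent
  P <- gf()   # regional precipitation latent
  D <- 0.5 * .zscore(-E) + 0.87 * gf()   # development favors lowlands

  elevation <- 2500 + 900 * E
  mix_t <- function(own) .zscore(0.5 * C - 0.4 * E + 0.77 * own)
  mix_p <- function(own) .zscore(0.5 * P + 0.87 * own)
  bio01 <- 8 + 5 * mix_t(gf())              # annual mean temperature, deg C
  bio10 <- 16 + 4 * mix_t(gf())             # hottest-quarter mean temperature
  bio12 <- pmax(50, 900 + 300 * mix_p(gf())) # annual precipitation, mm
  bio13 <- pmax(10, 180 + 60 * mix_p(gf()))  # wettest-month precipitation
  bio15 <- pmax(5, 60 + 20 * .zscore(0.3 * P + 0.95 * gf())) # seasonality

  gx <- (cbind(elevation[, -1], elevation[, nc]) -
           cbind(elevation[, 1], elevation[, -nc])) / (2 * params$cell_size)
  gy <- (rbind(elevation[1, ], elevation[-nr, ]) -
           rbind(elevation[-1, ], elevation[nr, ])) / (2 * params$cell_size)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (270 - atan2(gy, gx) * 180 / pi) %% 360

  soil_ph <- 6.5 + 0.8 * .zscore(0.3 * P + 0.95 * gf())
  soil_clay <- pmin(70, pmax(2, 25 + 8 * gf()))
  soil_sand <- pmin(90, pmax(5, 40 + 10 * gf()))
  soil_organic <- pmax(1, 25 + 10 * .zscore(0.3 * C + 0.95 * gf()))

  veg_levels <- c("conifer_forest", "broadleaf_forest", "mixed_forest",
                  "shrubland", "grassland", "bare")
  vlat <- .zscore(0.4 * .zscore(bio12) - 0.3 * E + 0.86 * gf())
  vq <- stats::quantile(vlat, c(0.22, 0.44, 0.60, 0.75, 0.90))
  vegetation <- matrix(findInterval(vlat, vq) + 1L, nr, nc)

  ## human source layers --------------------------------------------------
  population <- exp(2 + 1.8 * .zscore(D) + 0.3 * matrix(stats::rnorm(nr * nc), nr, nc))
  nightlight <- exp(1.2 * .zscore(D) + 0.5 * matrix(stats::rnorm(nr * nc), nr, nc))
  lu_levels <- c("construction", "arable", "irrigation", "forest", "grassland", "other")
  lu <- matrix("grassland", nr, nc)
  lu[vegetation <= 3] <- "forest"
  lu[elevation > stats::quantile(elevation, 0.97)] <- "other"
  dq <- stats::quantile(D, c(0.87, 0.90, 0.98))
  lu[D > dq[1] & D <= dq[2]] <- "irrigation"
  lu[D > dq[2] & D <= dq[3]] <- "arable"
  lu[D > dq[3]] <- "construction"
  landuse <- matrix(match(lu, lu_levels), nr, nc)

  roads <- .generate_roads(grid, params$n_roads_per_class)
  counties <- .generate_counties(grid, params$n_counties)
  livestock <- generate_livestock(counties,
                                  seed = params$seed + 104729L)

  rl <- function(m) raster_layer(grid, m)
  env <- predictor_stack(
    layers = list(bio01 = rl(bio01), bio10 = rl(bio10), bio12 = rl(bio12),
                  bio13 = rl(bio13), bio15 = rl(bio15),
                  elevation = rl(elevation), slope = rl(slope), aspect = rl(aspect),
                  vegetation = rl(vegetation),
                  soil_ph = rl(soil_ph), soil_clay = rl(soil_clay),
                  soil_sand = rl(soil_sand), soil_organic = rl(soil_organic)),
    categorical = list(vegetation = veg_levels))

  lu_raster <- rl(landuse)
  attr(lu_raster, "levels") <- lu_levels
  structure(list(params = params, grid = grid, env = env,
                 human = list(population = rl(population),
                              nightlight = rl(nightlight),
                              landuse = lu_raster, roads = roads),
                 counties = counties, livestock = livestock),
            class = "landscape")
}

.generate_roads <- function(grid, n_per_class) {
  xmin <- grid$origin_x; xmax <- grid$origin_x + grid$n_cols * grid$cell_size
  ymax <- grid$origin_y; ymin <- grid$origin_y - grid$n_rows * grid$cell_size
  geoms <- list(); cls <- character(0)
  for (k in names(n_per_class)) {
    for (i in seq_len(n_per_class[[k]])) {
      horiz <- stats::runif(1) < 0.5
      if (horiz) {
        xs <- sort(c(xmin, stats::runif(3, xmin, xmax), xmax))
        ys <- stats::runif(5, ymin, ymax)
        ys[2:4] <- ys[1] + cumsum(stats::rnorm(3, 0, (ymax - ymin) / 10))
        ys <- pmin(ymax, pmax(ymin, ys))
      } else {
        ys <- sort(c(ymin, stats::runif(3, ymin, ymax), ymax))
        xs <- stats::runif(5, xmin, xmax)
        xs[2:4] <- xs[1] + cumsum(stats::rnorm(3, 0, (xmax - xmin) / 10))
        xs <- pmin(xmax, pmax(xmin, xs))
      }
      geoms[[length(geoms) + 1L]] <- list(type = "line", coords = cbind(xs, ys))
      cls <- c(cls, k)
    }
  }
  feature_set(geoms, data.frame(road_class = cls, stringsAsFactors = FALSE),
              crs_id = grid$crs_id)
}

## Rectangular partition: factorize n_counties as r x c (closest factor pair)
## and cut rows/columns at randomized breakpoints (every strip >= 2 cells).
.generate_counties <- function(grid, n_counties) {
  r <- floor(sqrt(n_counties))
  while (n_counties %% r != 0) r <- r - 1
  cpart <- n_counties %/% r
  cuts <- function(n, k) {
    if (k == 1) return(n)
    w <- 2L + as.vector(stats::rmultinom(1, n - 2L * k, rep(1, k)))
    w
  }
  rw <- cuts(grid$n_rows, r); cw <- cuts(grid$n_cols, cpart)
  rb <- c(0, cumsum(rw)); cb <- c(0, cumsum(cw))
  geoms <- list(); ids <- character(0)
  idx <- 0L
  for (i in seq_len(r)) for (j in seq_len(cpart)) {
    idx <- idx + 1L
    x0 <- grid$origin_x + cb[j] * grid$cell_size
    x1 <- grid$origin_x + cb[j + 1] * grid$cell_size
    y0 <- grid$origin_y - rb[i] * grid$cell_size
    y1 <- grid$origin_y - rb[i + 1] * grid$cell_size
    geoms[[idx]] <- cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
    ids <- c(ids, sprintf("C%02d", idx))
  }
  county_table(county_id = ids, name = sprintf("County %s", sub("^C", "", ids)),
               geometry = geoms)
}

#' Generate a county livestock table
#'
#' Cattle and sheep head counts are log-normal across counties (a standard
#' shape for statistical-yearbook livestock data), non-negative integers,
#' reproducible under a fixed seed.
#'
#' @param counties A `county_table`.
#' @param seed Integer seed.
#' @return Data frame with `county_id`, `cattle`, `sheep`.
#' @export
generate_livestock <- function(counties, seed = 1L) {
  stopifnot(nrow(counties) > 0)
  set.seed(seed)
  n <- nrow(counties)
  data.frame(county_id = counties$county_id,
             cattle = as.integer(round(exp(stats::rnorm(n, 9.2, 0.8)))),
             sheep = as.integer(round(exp(stats::rnorm(n, 10.4, 0.8)))),
             stringsAsFactors = FALSE)
}

#' Life-form niche parameters for occurrence simulation
#'
#' Presence probability in a cell is
#' `plogis(intercept + sum(coeff * z(layer)) + noise)`, where each continuous
#' layer is z-scored over valid cells and categorical layers first pass
#' through a per-class preference score (`class_scores`) before z-scoring.
#' Coefficients are therefore on a common scale-free footing.
#'
#' @param lifeform One of `"terrestrial"`, `"epiphytic"`,
#'   `"mycoheterotrophic"`.
#' @param coefficients Named numeric vector of niche weights (names are
#'   predictor-stack layers); at least one must be nonzero unless all are
#'   zero for an explicit no-signal null.
#' @param intercept Baseline logit.
#' @param n_points Number of occurrence points to draw (>= 20 for presets).
#' @param sampling_noise SD of cell-level logit noise (>= 0).
#' @param class_scores Named list of per-class preference vectors for
#'   categorical layers referenced by `coefficients`.
#' @return A list of class `niche_params`.
#' @export
niche_params <- function(lifeform, coefficients, intercept, n_points,
                         sampling_noise = 0.5, class_scores = NULL) {
  lifeform <- match.arg(lifeform, c("terrestrial", "epiphytic", "mycoheterotrophic"))
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            sampling_noise >= 0, n_points >= 1)
  if (is.null(class_scores)) {
    class_scores <- list(vegetation = c(conifer_forest = 1, broadleaf_forest = 0.6,
                                        mixed_forest = 0.8, shrubland = 0.3,
                                        grassland = 0.1, bare = 0))
  }
  structure(list(lifeform = lifeform, coefficients = coefficients,
                 intercept = intercept, n_points = as.integer(n_points),
                 sampling_noise = sampling_noise, class_scores = class_scores),
            class = "niche_params")
}

#' Default niche presets for the three life forms
#'
#' The terrestrial niche is broad (moderate weights spread over temperature,
#' precipitation, elevation and soil), the epiphytic niche is driven by
#' precipitation (wettest-month amount and seasonality) and warm-season
#' temperature, and the mycoheterotrophic niche by vegetation and (cooler)
#' hottest-quarter temperature. Default sample sizes are strongly unequal
#' (2000 / 200 / 80 for terrestrial / mycoheterotrophic / epiphytic),
#' mirroring the order-of-magnitude imbalance of real orchid records.
#'
#' @return Named list of `niche_params` (`t`, `e`, `m`).
#' @export
niche_presets <- function() {
  list(
    t = niche_params("terrestrial",
                     c(bio01 = 2.0, bio12 = 1.6, elevation = -1.6, soil_ph = 1.0),
                     intercept = -6, n_points = 2000L, sampling_noise = 0.25),
    e = niche_params("epiphytic",
                     c(bio13 = 4.0, bio15 = 2.5, bio10 = 2.5),
                     intercept = -10, n_points = 80L, sampling_noise = 0.25),
    m = niche_params("mycoheterotrophic",
                     c(vegetation = 3.0, bio10 = -2.5, bio13 = 1.2),
                     intercept = -7.5, n_points = 200L, sampling_noise = 0.25)
  )
}

#' Standardized niche covariate for one layer
#' @noRd
.niche_covariate <- function(stack, nm, class_scores) {
  if (!nm %in% names(stack$layers)) stop("niche coefficient names unknown layer: ", nm)
  v <- raster_values_vec(stack$layers[[nm]])
  if (nm %in% names(stack$categorical)) {
    levels <- stack$categorical[[nm]]
    pref <- class_scores[[nm]]
    if (is.null(pref)) stop("no class_scores supplied for categorical layer ", nm)
    v <- unname(pref[levels[v]])
  }
  m <- is.finite(v)
  (v - mean(v[m])) / stats::sd(v[m])
}

#' Simulate life-form occurrences from a niche
#'
#' Cells are proposed uniformly over valid cells and accepted by a Bernoulli
#' draw with the cell's logistic suitability; accepted points are placed at
#' cell centers. Sampling continues until `n_points` presences are collected
#' or an iteration cap is hit (then an error reports the shortfall).
#'
#' @param stack A `predictor_stack` (environmental layers).
#' @param niche A [niche_params()] object.
#' @param seed Integer seed.
#' @return An `occurrence_set` data frame (`lon`, `lat`, `taxon`, `lifeform`).
#' @export
generate_occurrences <- function(stack, niche, seed = 1L) {
  set.seed(seed)
  valid <- which(stack_mask(stack))
  eta <- rep(niche$intercept, n_cells(stack$grid))
  for (nm in names(niche$coefficients)) {
    eta <- eta + niche$coefficients[[nm]] * .niche_covariate(stack, nm, niche$class_scores)
  }
  if (niche$sampling_noise > 0) {
    eta <- eta + stats::rnorm(length(eta), 0, niche$sampling_noise)
  }
  p <- stats::plogis(eta)
  n <- niche$n_points
  got <- integer(0)
  draws <- 0L; cap <- 500L * n
  while (length(got) < n && draws < cap) {
    take <- min(4L * n, cap - draws)
    cand <- sample(valid, take, replace = TRUE)
    acc <- stats::runif(take) < p[cand]
    got <- c(got, cand[acc])
    draws <- draws + take
  }
  if (length(got) < n) {
    stop(sprintf("suitability too low: only %d of %d occurrences after %d draws",
                 length(got), n, draws))
  }
  got <- got[seq_len(n)]
  ctr <- cell_centers(stack$grid, got)
  taxon <- sprintf("%s_sp%02d", substr(niche$lifeform, 1, 3),
                   sample.int(12L, n, replace = TRUE))
  occurrence_set(data.frame(lon = ctr[, "x"], lat = ctr[, "y"],
                            taxon = taxon, lifeform = niche$lifeform,
                            stringsAsFactors = FALSE))
}

#' Export a synthetic landscape to disk
#'
#' Writes every raster layer as an ASCII grid, roads and counties as GeoJSON,
#' the livestock table as CSV, and a JSON manifest listing layer names and
#' roles.
#'
#' @param landscape A `landscape`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(landscape$env$layers)) {
    write_raster(landscape$env$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  for (nm in c("population", "nightlight", "landuse")) {
    write_raster(landscape$human[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  write_features(landscape$human$roads, file.path(dir, "roads.geojson"))
  geom <- county_geometry(landscape$counties)
  cf <- feature_set(lapply(geom, function(g) list(type = "polygon", coords = g)),
                    as.data.frame(landscape$counties),
                    crs_id = landscape$grid$crs_id)
  write_features(cf, file.path(dir, "counties.geojson"))
  utils::write.csv(landscape$livestock, file.path(dir, "livestock.csv"),
                   row.names = FALSE)
  manifest <- list(
    crs_id = landscape$grid$crs_id,
    seed = landscape$params$seed,
    env_layers = names(landscape$env$layers),
    categorical = landscape$env$categorical,
    roles = list(hottest_quarter_temperature = "bio10",
                 wettest_month_precipitation = "bio13",
                 precipitation_seasonality = "bio15"),
    human_layers = c("population", "nightlight", "landuse"),
    landuse_levels = attr(landscape$human$landuse, "levels"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
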