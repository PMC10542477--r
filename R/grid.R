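#' Grid specification for a shared analysis grid
#'
#' All layers in one analysis share a single `grid_spec`: an equal-area
#' projected grid identified by its top-left corner, cell size and
#' dimensions. Cell area is `cell_size^2` (1 km2 at the 1000 m default),
#' which is what makes county areas in km2 a plain cell count.
#'
#' Grid indexing is row-major from the top-left origin. Cell `(r, c)` spans
#' the half-open intervals `[origin_x + (c-1)*cell_size, origin_x + c*cell_size)`
#' in x and `(origin_y - r*cell_size, origin_y - (r-1)*cell_size]` in y.
#'
#' @param origin_x,origin_y Projected coordinates (m) of the top-left grid
#'   corner.
#' @param cell_size Cell edge length in metres (default 1000).
#' @param n_rows,n_cols Grid dimensions.
#' @param crs_id Identifier of the equal-area projected CRS the coordinates
#'   live in. There is no default: area arithmetic is only meaningful in a
#'   projection the user vouches for.
#' @param nodata Sentinel value used for masked cells on disk.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size = 1000, n_rows, n_cols,
                      crs_id, nodata = -9999) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  if (missing(crs_id) || !nzchar(crs_id)) {
    stop("grid_spec() requires an explicit equal-area 'crs_id'")
  }
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), n_rows = n_rows, n_cols = n_cols,
         crs_id = as.character(crs_id), nodata = as.numeric(nodata)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g), CRS %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' Test whether two grid specifications describe the same grid
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  isTRUE(a$origin_x == b$origin_x) && isTRUE(a$origin_y == b$origin_y) &&
    isTRUE(a$cell_size == b$cell_size) && a$n_rows == b$n_rows &&
    a$n_cols == b$n_cols && a$crs_id == b$crs_id
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Raster layer on an analysis grid
#'
#' A raster couples a `grid_spec` with an `n_rows x n_cols` value matrix and
#' a logical validity mask. Values must be finite wherever the mask is TRUE;
#' masked cells carry `NA`.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix (`n_rows x n_cols`) or vector in row-major
#'   cell order.
#' @param mask Optional logical matrix; defaults to `is.finite(values)`.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values)) {
    stopifnot(length(values) == n_cells(grid))
    values <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  }
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (is.null(mask)) mask <- is.finite(values)
  if (!is.matrix(mask)) mask <- matrix(mask, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  if (any(mask & !is.finite(values))) {
    stop("raster values must be finite wherever the mask is TRUE")
  }
  values[!mask] <- NA_real_
  structure(list(grid = grid, values = values, mask = mask), class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("<raster_layer> %d x %d, %d valid cells, range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

## -- cell index helpers (row-major, 1-based) ---------------------------------

cell_rc <- function(grid, cell) {
  cell <- as.integer(cell)
  r <- (cell - 1L) %/% grid$n_cols + 1L
  c <- (cell - 1L) %% grid$n_cols + 1L
  cbind(row = r, col = c)
}

rc_cell <- function(grid, r, c) (as.integer(r) - 1L) * grid$n_cols + as.integer(c)

#' Cell-center coordinates for cell indices
#' @param grid A `grid_spec`.
#' @param cell Integer cell indices (row-major); defaults to all cells.
#' @return Two-column matrix of x/y coordinates.
#' @export
cell_centers <- function(grid, cell = seq_len(n_cells(grid))) {
  rc <- cell_rc(grid, cell)
  cbind(x = grid$origin_x + (rc[, "col"] - 0.5) * grid$cell_size,
        y = grid$origin_y - (rc[, "row"] - 0.5) * grid$cell_size)
}

#' Map point coordinates to cell indices
#'
#' Uses half-open cell intervals (see [grid_spec()]); points outside the grid
#' extent map to `NA`.
#' @param grid A `grid_spec`.
#' @param x,y Coordinate vectors.
#' @return Integer vector of row-major cell indices.
#' @export
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  ## points exactly on the top edge belong to row 1
  row[grid$origin_y - y == 0] <- 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_integer_, length(x))
  out[ok] <- rc_cell(grid, row[ok], col[ok])
  out
}

raster_values_vec <- function(raster) as.vector(t(raster$values))
raster_mask_vec <- function(raster) as.vector(t(raster$mask))

## -- file I/O ----------------------------------------------------------------

#' Read / write a raster as an Esri ASCII grid
#'
#' Rasters are stored in the plain-text Esri ASCII grid format (`.asc`) with
#' full double precision (`%.17g`), so a write/read round trip is bit-exact.
#' A JSON sidecar (`<path>.json`) carries the CRS identifier, which the `.asc`
#' header cannot.
#'
#' @param path Path to the `.asc` file.
#' @param grid Optional session `grid_spec`. If supplied, the file must match
#'   it exactly (cell size, dimensions, origin, CRS); a mismatch is an error,
#'   never a silent resampling or reprojection.
#' @return `read_raster()` returns a `raster_layer`; `write_raster()` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  side <- paste0(path, ".json")
  crs_id <- if (file.exists(side)) jsonlite::fromJSON(side)$crs_id else "unspecified"
  gs <- grid_spec(origin_x = hdr$xllcorner,
                  origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                  cell_size = hdr$cellsize, n_rows = hdr$nrows, n_cols = hdr$ncols,
                  crs_id = crs_id, nodata = hdr$nodata_value)
  if (!is.null(grid)) {
    if (gs$cell_size != grid$cell_size) {
      stop(sprintf("cell size mismatch: file has %g m, session grid has %g m",
                   gs$cell_size, grid$cell_size))
    }
    if (!same_grid(gs, grid)) {
      stop("raster grid does not match the session grid (origin/dimensions/CRS)")
    }
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  stopifnot(length(vals) == gs$n_rows * gs$n_cols)
  m <- matrix(vals, nrow = gs$n_rows, ncol = gs$n_cols, byrow = TRUE)
  mask <- m != gs$nodata
  m[!mask] <- NA_real_
  raster_layer(gs, m, mask)
}

#' @rdname read_raster
#' @param raster A `raster_layer` to write.
#' @export
write_raster <- function(raster, path) {
  g <- raster$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin_x),
    sprintf("yllcorner %.17g", g$origin_y - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", g$nodata)
  ), con)
  vals <- raster$values
  vals[!raster$mask] <- g$nodata
  for (r in seq_len(g$n_rows)) {
    writeLines(paste(sprintf("%.17g", vals[r, ]), collapse = " "), con)
  }
  jsonlite::write_json(list(crs_id = g$crs_id), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

## -- alignment ---------------------------------------------------------------

#' Resample a raster onto a target grid
#'
#' Source and target must share a CRS; this is resampling, not reprojection.
#' `nearest` takes the source cell containing each target cell center;
#' `mean` averages the source cells whose centers fall inside each target
#' cell (block mean). Categorical layers must use `nearest`.
#'
#' @param raster A `raster_layer`.
#' @param target Target `grid_spec`.
#' @param method `"nearest"` or `"mean"`.
#' @param categorical Is the layer categorical? (`mean` then errors.)
#' @return A `raster_layer` on `target`.
#' @export
align_to_grid <- function(raster, target, method = c("nearest", "mean"),
                          categorical = FALSE) {
  method <- match.arg(method)
  src <- raster$grid
  if (src$crs_id != target$crs_id) {
    stop("CRS mismatch (", src$crs_id, " vs ", target$crs_id,
         "): align_to_grid() never reprojects")
  }
  if (categorical && method == "mean") {
    stop("categorical layers must be aligned with method = 'nearest'")
  }
  if (same_grid(src, target)) return(raster_layer(target, raster$values, raster$mask))
  vsrc <- raster_values_vec(raster)
  msrc <- raster_mask_vec(raster)
  if (method == "nearest") {
    ctr <- cell_centers(target)
    idx <- xy_to_cell(src, ctr[, "x"], ctr[, "y"])
    vals <- ifelse(is.na(idx), NA_real_, vsrc[idx])
    mask <- !is.na(idx) & msrc[idx]
    vals[!mask] <- NA_real_
    raster_layer(target, vals, mask)
  } else {
    ctr <- cell_centers(src)
    tgt <- xy_to_cell(target, ctr[, "x"], ctr[, "y"])
    keep <- !is.na(tgt) & msrc
    sums <- rep(0, n_cells(target)); cnts <- rep(0L, n_cells(target))
    tt <- tgt[keep]
    sums[seq_len(n_cells(target))] <- 0
    agg <- tapply(vsrc[keep], tt, sum)
    cnt <- tapply(rep(1L, sum(keep)), tt, sum)
    ids <- as.integer(names(agg))
    vals <- rep(NA_real_, n_cells(target))
    vals[ids] <- as.numeric(agg) / as.numeric(cnt)
    raster_layer(target, vals, !is.na(vals))
  }
}

## -- vector features ---------------------------------------------------------

#' Vector feature set (points, lines, polygons) in the grid CRS
#'
#' @param geoms List of geometries, each a list with `type`
#'   (`"point"`, `"line"` or `"polygon"`) and `coords` (two-column matrix).
#' @param attributes Data frame of per-feature attributes (one row per
#'   geometry), or `NULL`.
#' @param crs_id CRS identifier the coordinates live in.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(geoms, attributes = NULL, crs_id = "unspecified") {
  stopifnot(is.list(geoms))
  for (g in geoms) {
    stopifnot(g$type %in% c("point", "line", "polygon"), is.matrix(g$coords),
              ncol(g$coords) == 2)
  }
  if (is.null(attributes)) attributes <- data.frame(row.names = seq_along(geoms))
  stopifnot(nrow(attributes) == length(geoms))
  structure(list(geoms = geoms, attributes = attributes, crs_id = crs_id),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features (%s), CRS %s\n", length(x$geoms),
              paste(names(table(vapply(x$geoms, `[[`, "", "type"))), collapse = "/"),
              x$crs_id))
  invisible(x)
}

#' Euclidean distance from every cell center to the nearest feature
#'
#' @param grid A `grid_spec`.
#' @param features A `feature_set` of points and/or lines in the grid CRS.
#' @return A `raster_layer` of distances in metres (0 on features).
#' @export
distance_to_features <- function(grid, features) {
  stopifnot(inherits(features, "feature_set"))
  if (length(features$geoms) == 0) {
    stop("distance_to_features() needs a non-empty feature set")
  }
  ctr <- cell_centers(grid)
  px <- ctr[, "x"]; py <- ctr[, "y"]
  d2 <- rep(Inf, length(px))
  for (g in features$geoms) {
    cc <- g$coords
    if (g$type == "point" || nrow(cc) == 1) {
      for (i in seq_len(nrow(cc))) {
        d2 <- pmin(d2, (px - cc[i, 1])^2 + (py - cc[i, 2])^2)
      }
    } else if (g$type == "line") {
      for (i in seq_len(nrow(cc) - 1)) {
        d2 <- pmin(d2, .dist2_segment(px, py, cc[i, 1], cc[i, 2], cc[i + 1, 1], cc[i + 1, 2]))
      }
    } else {
      stop("distance_to_features() supports point and line geometries only")
    }
  }
  raster_layer(grid, sqrt(d2))
}

.dist2_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

## -- counties and zonal statistics ------------------------------------------

#' County table: administrative polygons with areas
#'
#' @param county_id Unique county identifiers (coerced to character).
#' @param name County names (defaults to the ids).
#' @param geometry List of polygon rings (two-column coordinate matrices,
#'   closed or open; closure is implied).
#' @param area_km2 Optional areas; computed from the polygons (shoelace
#'   formula, m2 to km2) when missing.
#' @return A data frame of class `county_table` carrying the geometry as an
#'   attribute.
#' @export
county_table <- function(county_id, name = county_id, geometry, area_km2 = NULL) {
  county_id <- as.character(county_id)
  stopifnot(!anyDuplicated(county_id), length(geometry) == length(county_id))
  if (is.null(area_km2)) {
    area_km2 <- vapply(geometry, .polygon_area_m2, numeric(1)) / 1e6
  }
  stopifnot(all(area_km2 > 0))
  df <- data.frame(county_id = county_id, name = as.character(name),
                   area_km2 = area_km2, stringsAsFactors = FALSE)
  names(geometry) <- county_id
  attr(df, "geometry") <- geometry
  class(df) <- c("county_table", "data.frame")
  df
}

#' Polygon geometries of a county table
#' @param counties A `county_table`.
#' @return Named list of polygon coordinate matrices.
#' @export
county_geometry <- function(counties) attr(counties, "geometry")

.polygon_area_m2 <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Point-in-polygon test (even-odd ray casting)
#' @param px,py Point coordinate vectors.
#' @param poly Two-column polygon ring matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Assign grid cells to counties by cell-center membership
#'
#' A cell belongs to the county whose polygon contains its center; when
#' polygons overlap within tolerance, the lowest `county_id` wins.
#' @param grid A `grid_spec`.
#' @param counties A `county_table`.
#' @return Integer vector (per cell) of row indices into `counties`, `NA`
#'   where no county covers the cell.
#' @export
county_assignment <- function(grid, counties) {
  ctr <- cell_centers(grid)
  geom <- county_geometry(counties)
  ord <- order(counties$county_id)
  assign <- rep(NA_integer_, nrow(ctr))
  for (i in ord) {
    todo <- is.na(assign)
    if (!any(todo)) break
    hit <- point_in_polygon(ctr[todo, "x"], ctr[todo, "y"], geom[[i]])
    assign[which(todo)[hit]] <- i
  }
  assign
}

#' Per-county area of a binary suitability raster
#'
#' Counts value-1 cells whose centers fall in each county polygon and
#' multiplies by the cell area. Cells covered by no county are counted in no
#' county and reported via `message()`.
#'
#' @param binary A `raster_layer` with values in `{0, 1}` on its mask.
#' @param counties A `county_table`.
#' @param assignment Optional precomputed [county_assignment()] (a speed-up
#'   when summarising many maps over one county table).
#' @return Data frame with `county_id` and `area_km2`.
#' @export
zonal_area <- function(binary, counties, assignment = NULL) {
  v <- raster_values_vec(binary)
  m <- raster_mask_vec(binary)
  if (any(!(v[m] %in% c(0, 1)))) stop("zonal_area() needs a binary 0/1 raster")
  if (is.null(assignment)) assignment <- county_assignment(binary$grid, counties)
  uncovered <- sum(m & is.na(assignment))
  if (uncovered > 0) {
    message(uncovered, " valid cells fall in no county polygon and are uncounted")
  }
  cell_km2 <- (binary$grid$cell_size / 1000)^2
  ones <- m & !is.na(v) & v == 1
  counts <- tapply(ones, assignment, sum)
  out <- data.frame(county_id = counties$county_id, area_km2 = 0)
  out$area_km2[as.integer(names(counts))] <- as.numeric(counts) * cell_km2
  out
}

## -- GeoJSON I/O -------------------------------------------------------------

#' Read / write feature sets as GeoJSON
#'
#' Geometries are stored as standard GeoJSON Point/LineString/Polygon
#' features; the grid CRS identifier travels in a top-level `crs_id` member
#' (GeoJSON itself is CRS-agnostic).
#'
#' @param path File path.
#' @return `read_features()` returns a `feature_set`.
#' @export
read_features <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- list(); attrs <- list()
  for (f in js$features) {
    ty <- f$geometry$type
    co <- f$geometry$coordinates
    if (ty == "Point") {
      coords <- matrix(unlist(co), ncol = 2, byrow = TRUE); type <- "point"
    } else if (ty == "LineString") {
      coords <- do.call(rbind, lapply(co, function(p) unlist(p))); type <- "line"
    } else if (ty == "Polygon") {
      coords <- do.call(rbind, lapply(co[[1]], function(p) unlist(p))); type <- "polygon"
    } else stop("unsupported GeoJSON geometry: ", ty)
    geoms[[length(geoms) + 1L]] <- list(type = type, coords = coords)
    attrs[[length(attrs) + 1L]] <- as.data.frame(f$properties, stringsAsFactors = FALSE)
  }
  attributes <- if (length(attrs) && ncol(attrs[[1]])) do.call(rbind, attrs) else NULL
  feature_set(geoms, attributes, crs_id = js$crs_id %||% "unspecified")
}

#' @rdname read_features
#' @param features A `feature_set`.
#' @export
write_features <- function(features, path) {
  to_coords <- function(g) {
    if (g$type == "point") as.numeric(g$coords[1, ])
    else if (g$type == "line") lapply(seq_len(nrow(g$coords)), function(i) as.numeric(g$coords[i, ]))
    else list(lapply(seq_len(nrow(g$coords)), function(i) as.numeric(g$coords[i, ])))
  }
  feats <- lapply(seq_along(features$geoms), function(i) {
    g <- features$geoms[[i]]
    props <- if (ncol(features$attributes)) as.list(features$attributes[i, , drop = FALSE]) else NULL
    list(type = "Feature",
         geometry = list(
           type = switch(g$type, point = "Point", line = "LineString", polygon = "Polygon"),
           coordinates = to_coords(g)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", crs_id = features$crs_id,
                            features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a polygon feature set to a county table
#' @param features A `feature_set` of polygons with `county_id` (and
#'   optionally `name`, `area_km2`) attributes.
#' @return A `county_table`.
#' @export
as_county_table <- function(features) {
  stopifnot(all(vapply(features$geoms, `[[`, "", "type") == "polygon"))
  at <- features$attributes
  county_table(county_id = at$county_id,
               name = if ("name" %in% names(at)) at$name else at$county_id,
               geometry = lapply(features$geoms, `[[`, "coords"),
               area_km2 = if ("area_km2" %in% names(at)) at$area_km2 else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
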