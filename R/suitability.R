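#' Binarize a suitability raster at a threshold
#'
#' A cell is suitable (1) when suitability is strictly greater than the
#' threshold ("more than" 0.5 by default), otherwise 0; the mask is
#' preserved.
#'
#' @param suitability A `raster_layer` with values in `[0, 1]`.
#' @param threshold Cut-off (default 0.5).
#' @return A binary `raster_layer` (class also `binary_map`).
#' @export
binarize <- function(suitability, threshold = 0.5) {
  v <- raster_values_vec(suitability); m <- raster_mask_vec(suitability)
  if (any(v[m] < 0 | v[m] > 1)) stop("suitability values outside [0, 1]")
  out <- rep(NA_real_, length(v))
  out[m] <- as.numeric(v[m] > threshold)
  r <- raster_layer(suitability$grid, out,
                    matrix(m, suitability$grid$n_rows, suitability$grid$n_cols,
                           byrow = TRUE))
  class(r) <- c("binary_map", class(r))
  r
}

.check_binary <- function(x) {
  v <- raster_values_vec(x); m <- raster_mask_vec(x)
  if (any(!(v[m] %in% c(0, 1)))) stop("not a binary 0/1 raster")
  invisible(TRUE)
}

#' Fuse life-form binary maps into a total layer
#'
#' Cell-wise logical OR of the terrestrial, epiphytic and mycoheterotrophic
#' binary maps.
#'
#' @param t,e,m Binary `raster_layer`s on one shared grid.
#' @return A binary `raster_layer`.
#' @export
fuse_lifeform_layers <- function(t, e, m) {
  maps <- list(t, e, m)
  for (x in maps) {
    if (!same_grid(x$grid, t$grid)) stop("grid mismatch between life-form layers")
    .check_binary(x)
  }
  vals <- pmax(raster_values_vec(t), raster_values_vec(e), raster_values_vec(m))
  mask <- raster_mask_vec(t) & raster_mask_vec(e) & raster_mask_vec(m)
  vals[!mask] <- NA_real_
  r <- raster_layer(t$grid, vals, matrix(mask, t$grid$n_rows, t$grid$n_cols,
                                         byrow = TRUE))
  class(r) <- c("binary_map", class(r))
  r
}

#' Changed area between two binary maps
#'
#' The symmetric difference of two binary maps, its area, and its percentage
#' of the supplied total study area.
#'
#' @param a,b Binary `raster_layer`s on one grid.
#' @param total_area_km2 Total study area (default: unmasked cells times cell
#'   area).
#' @return A list of class `change_map`: `raster` (0/1 changed cells),
#'   `changed_area_km2`, `changed_pct`.
#' @export
changed_area <- function(a, b, total_area_km2 = NULL) {
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch")
  .check_binary(a); .check_binary(b)
  mask <- raster_mask_vec(a) & raster_mask_vec(b)
  diff <- as.numeric(raster_values_vec(a) != raster_values_vec(b))
  diff[!mask] <- NA_real_
  cell_km2 <- (a$grid$cell_size / 1000)^2
  if (is.null(total_area_km2)) total_area_km2 <- sum(mask) * cell_km2
  area <- sum(diff[mask]) * cell_km2
  structure(list(raster = raster_layer(a$grid, diff,
                                       matrix(mask, a$grid$n_rows, a$grid$n_cols,
                                              byrow = TRUE)),
                 changed_area_km2 = area,
                 changed_pct = area / total_area_km2 * 100),
            class = "change_map")
}

#' Suitable-area summary per map and county
#'
#' For each binary map: the total suitable area (km2), its percentage of the
#' study area, and the per-county areas from [zonal_area()].
#'
#' @param maps Named list of binary `raster_layer`s.
#' @param counties A `county_table`.
#' @param total_area_km2 Study-area total (default from the first map's
#'   mask).
#' @param assignment Optional precomputed [county_assignment()].
#' @return List with `totals` (data frame: map, suitable_km2, pct) and
#'   `by_county` (data frame: map, county_id, area_km2).
#' @export
suitable_area_summary <- function(maps, counties, total_area_km2 = NULL,
                                  assignment = NULL) {
  stopifnot(length(maps) > 0, !is.null(names(maps)))
  g <- maps[[1]]$grid
  cell_km2 <- (g$cell_size / 1000)^2
  if (is.null(total_area_km2)) total_area_km2 <- sum(maps[[1]]$mask) * cell_km2
  if (is.null(assignment)) assignment <- county_assignment(g, counties)
  totals <- data.frame(); by_county <- data.frame()
  for (nm in names(maps)) {
    .check_binary(maps[[nm]])
    v <- raster_values_vec(maps[[nm]]); m <- raster_mask_vec(maps[[nm]])
    tot <- sum(v[m]) * cell_km2
    totals <- rbind(totals, data.frame(map = nm, suitable_km2 = tot,
                                       pct = tot / total_area_km2 * 100))
    za <- zonal_area(maps[[nm]], counties, assignment = assignment)
    by_county <- rbind(by_county, data.frame(map = nm, za))
  }
  list(totals = totals, by_county = by_county, total_area_km2 = total_area_km2)
}
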