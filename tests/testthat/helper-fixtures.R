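# Small fixtures shared across test files; everything is built in code.

tiny_grid <- function(n_rows = 5, n_cols = n_rows, cell = 1000,
                      crs = "synthetic:laea") {
  grid_spec(origin_x = 0, origin_y = n_rows * cell, cell_size = cell,
            n_rows = n_rows, n_cols = n_cols, crs_id = crs)
}

# raster from a row-major vector
rl <- function(grid, v) raster_layer(grid, v)

# a vertical road line at x spanning the full grid height
vline <- function(grid, x, class = "national_highway") {
  feature_set(list(list(type = "line",
                        coords = cbind(c(x, x),
                                       c(grid$origin_y,
                                         grid$origin_y - grid$n_rows * grid$cell_size)))),
              data.frame(road_class = class, stringsAsFactors = FALSE),
              crs_id = grid$crs_id)
}

# rectangle polygon from cell bounds [r1..r2] x [c1..c2] (1-based, inclusive)
rect_poly <- function(grid, r1, r2, c1, c2) {
  x0 <- grid$origin_x + (c1 - 1) * grid$cell_size
  x1 <- grid$origin_x + c2 * grid$cell_size
  y0 <- grid$origin_y - (r1 - 1) * grid$cell_size
  y1 <- grid$origin_y - r2 * grid$cell_size
  cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
}

# small landscape used by several module tests (not the study-scale default)
small_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_landscape(landscape_params(seed = 42, n_rows = 60,
                                                    n_cols = 60, n_counties = 9,
                                                    spatial_corr_length = 5))
    }
    cache
  }
})

make_occ <- function(grid, cells, lifeform = "terrestrial", taxon = "sp1") {
  ctr <- cell_centers(grid, cells)
  occurrence_set(data.frame(lon = ctr[, "x"], lat = ctr[, "y"],
                            taxon = taxon, lifeform = lifeform,
                            stringsAsFactors = FALSE))
}
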