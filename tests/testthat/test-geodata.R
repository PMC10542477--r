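test_that("raster round trip through disk is bit-exact, nodata respected", {
  g <- tiny_grid(3)
  set.seed(1)
  v <- rnorm(9) * 1e3
  v[4] <- NA
  r <- raster_layer(g, v)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_identical(r2$values, r$values)
  expect_identical(r2$mask, r$mask)
  expect_true(same_grid(r2$grid, g))

  all_na <- raster_layer(g, rep(NA_real_, 9))
  write_raster(all_na, path)
  r3 <- read_raster(path)
  expect_false(any(r3$mask))
})

test_that("reading against a mismatched session grid errors, naming both sizes", {
  g <- tiny_grid(3, cell = 500)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(raster_layer(g, 1:9), path)
  session <- tiny_grid(3, cell = 1000)
  expect_error(read_raster(path, grid = session), "500")
  expect_error(read_raster(path, grid = session), "1000")
  expect_error(read_raster("no/such/file.asc"), "not found")
})

test_that("align_to_grid: identity, block mean, nearest center rule", {
  src <- tiny_grid(2, cell = 500)
  r <- raster_layer(src, c(1, 1, 3, 3))
  expect_identical(align_to_grid(r, src)$values, r$values)

  tgt <- grid_spec(0, 1000, cell_size = 1000, n_rows = 1, n_cols = 1,
                   crs_id = src$crs_id)
  expect_equal(align_to_grid(r, tgt, "mean")$values[1, 1], 2.0)
  # target center (500, 500) lies in the bottom-right source cell (value 3)
  expect_equal(align_to_grid(r, tgt, "nearest")$values[1, 1], 3)
  expect_error(align_to_grid(r, tgt, "mean", categorical = TRUE), "nearest")
  other <- grid_spec(0, 1000, 1000, 1, 1, crs_id = "other-crs")
  expect_error(align_to_grid(r, other), "CRS")
})

test_that("distance_to_features matches exact geometry and brute force", {
  g <- tiny_grid(3, cell = 1000)
  road <- vline(g, 1500)  # passes through centers of column 2
  d <- distance_to_features(g, road)
  expect_equal(d$values[2, 2], 0)
  expect_equal(d$values[2, 1], 1000)
  expect_equal(d$values[2, 3], 1000)

  pt <- feature_set(list(list(type = "point",
                              coords = cbind(1500, 1500))), crs_id = g$crs_id)
  dp <- distance_to_features(g, pt)
  expect_equal(dp$values[2, 2], 0)
  expect_equal(dp$values[1, 2], 1000)  # 4-neighbour centers at one cell size
  expect_equal(dp$values[2, 1], 1000)

  # brute force on a 10x10 grid with 3 random points
  g10 <- tiny_grid(10, cell = 100)
  set.seed(7)
  pts <- cbind(runif(3, 0, 1000), runif(3, 0, 1000))
  fs <- feature_set(lapply(1:3, function(i) list(type = "point",
                                                 coords = pts[i, , drop = FALSE])),
                    crs_id = g10$crs_id)
  d2 <- distance_to_features(g10, fs)
  ctr <- cell_centers(g10)
  brute <- apply(ctr, 1, function(p) {
    min(sqrt((p[1] - pts[, 1])^2 + (p[2] - pts[, 2])^2))
  })
  expect_equal(as.vector(t(d2$values)), brute, tolerance = 1e-6)

  expect_error(distance_to_features(g, feature_set(list(), crs_id = g$crs_id)),
               "non-empty")
})

test_that("zonal_area counts suitable cells per county and is additive", {
  g <- tiny_grid(5)
  v <- rep(0, 25)
  expect_equal(sum(zonal_area(raster_layer(g, v),
                              county_table("A", geometry = list(rect_poly(g, 1, 5, 1, 5))))$area_km2),
               0)

  v[c(1, 3, 7, 11, 13, 20, 25)] <- 1  # 7 suitable cells
  one <- county_table("A", geometry = list(rect_poly(g, 1, 5, 1, 5)))
  expect_equal(zonal_area(raster_layer(g, v), one)$area_km2, 7)

  # split 3 / 4 across two disjoint counties (rows 1-2 hold cells 1,3,7; rest below)
  two <- county_table(c("A", "B"),
                      geometry = list(rect_poly(g, 1, 2, 1, 5), rect_poly(g, 3, 5, 1, 5)))
  za <- zonal_area(raster_layer(g, v), two)
  expect_equal(za$area_km2[za$county_id == "A"], 3)
  expect_equal(za$area_km2[za$county_id == "B"], 4)
  expect_equal(sum(za$area_km2), 7)  # additivity over a partition

  expect_error(zonal_area(raster_layer(g, rep(0.5, 25)), one), "binary")
})

test_that("GeoJSON round trip preserves geometries and attributes", {
  g <- tiny_grid(4)
  fs <- feature_set(list(list(type = "line", coords = cbind(c(0, 4000), c(0, 4000))),
                         list(type = "point", coords = cbind(500, 500))),
                    data.frame(road_class = c("railway", "village_highway"),
                               stringsAsFactors = FALSE),
                    crs_id = g$crs_id)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_features(fs, path)
  fs2 <- read_features(path)
  expect_equal(fs2$attributes$road_class, fs$attributes$road_class)
  expect_equal(fs2$geoms[[1]]$coords, fs$geoms[[1]]$coords, ignore_attr = TRUE)
  expect_equal(fs2$crs_id, g$crs_id)

  ct <- county_table(c("C1", "C2"),
                     geometry = list(rect_poly(g, 1, 4, 1, 2), rect_poly(g, 1, 4, 3, 4)))
  cf <- feature_set(lapply(county_geometry(ct), function(x) list(type = "polygon", coords = x)),
                    as.data.frame(ct), crs_id = g$crs_id)
  write_features(cf, path)
  ct2 <- as_county_table(read_features(path))
  expect_equal(ct2$county_id, ct$county_id)
  expect_equal(ct2$area_km2, ct$area_km2)
})
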