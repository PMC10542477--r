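test_that("road-access scores reproduce the published distance criteria", {
  g <- grid_spec(0, 300, cell_size = 100, n_rows = 3, n_cols = 3,
                 crs_id = "synthetic:laea")
  # vertical road 50 m right of the center column of cell centers (x = 150)
  sc <- score_access(g, vline(g, 200, "national_highway"))
  expect_equal(sc$raster$values[2, 2], 10)

  wide <- grid_spec(0, 100, cell_size = 100, n_rows = 1, n_cols = 60,
                    crs_id = "synthetic:laea")
  # village road at x = 0; cell centers at 50, 150, ..., distance 700 at col 8
  sv <- score_access(wide, vline(wide, 0, "village_highway"))
  expect_equal(sv$raster$values[1, 8], 1)   # 500-1000 m bin
  # railway at 2000 m -> 1000-3000 m bin scores 2
  sr <- score_access(wide, vline(wide, 0, "railway"))
  expect_equal(sr$raster$values[1, 21], 2)  # center 2050 m
  # beyond 3000 m every class scores 0
  expect_equal(sr$raster$values[1, 51], 0)  # center 5050 m

  # boundary values fall in the farther bin: exactly 90 m -> second bin
  gb <- grid_spec(0, 100, cell_size = 100, n_rows = 1, n_cols = 2,
                  crs_id = "synthetic:laea")
  sb <- score_access(gb, vline(gb, 140, "national_highway"))
  expect_equal(sb$raster$values[1, 1], 8)

  expect_error(score_access(g, vline(g, 0, "goat_track")), "goat_track")
})

test_that("access score is non-increasing with distance for a single class", {
  wide <- grid_spec(0, 100, cell_size = 50, n_rows = 1, n_cols = 100,
                    crs_id = "synthetic:laea")
  for (cls in access_table_default()$road_class) {
    s <- score_access(wide, vline(wide, 0, cls))
    expect_true(all(diff(s$raster$values[1, ]) <= 0))
    expect_true(all(s$raster$values >= 0 & s$raster$values <= 10))
  }
})

test_that("population scores follow the capped logarithmic rule", {
  g <- tiny_grid(2, 2)
  d <- raster_layer(g, c(1500, 0, 1000, 10))
  s <- score_population(d)
  expect_equal(s$raster$values[1, 1], 10)                 # above the cap
  expect_equal(s$raster$values[1, 2], 0)                  # log10(1) = 0
  expect_equal(s$raster$values[2, 1], 10, tolerance = 0.01)
  expect_equal(s$raster$values[2, 2], 3.333 * log10(11))
  expect_error(score_population(raster_layer(g, c(-1, 0, 0, 0))), "non-negative")
})

test_that("grazing scores hit the formula's fixed points", {
  g <- tiny_grid(4)
  ct <- county_table(c("A", "B", "C"),
                     geometry = list(rect_poly(g, 1, 4, 1, 2),
                                     rect_poly(g, 1, 4, 3, 3),
                                     rect_poly(g, 1, 4, 4, 4)))
  # areas: 8, 4, 4 km2. Pick sheep so x_B = x_max, x_A = sqrt(x_max).
  x_max <- 400
  recs <- data.frame(county_id = c("A", "B", "C"),
                     cattle = c(0, 0, 10),
                     sheep = c(sqrt(x_max) * 8, x_max * 4, 0))
  s <- score_grazing(recs, ct, g)
  expect_equal(s$raster$values[1, 3], 10)   # county with x_i = x_max
  expect_equal(s$raster$values[1, 1], 5)    # x_i = x_max^(1/2) -> score 5
  # one cattle head counts as five sheep: county C density = 50/4
  xi <- sheep_equivalent_density(recs, ct)
  expect_equal(xi$x_i[3], 50 / 4)
  expect_equal(5 * 10 + 0, 50)

  expect_error(score_grazing(transform(recs, cattle = 0, sheep = 0), ct, g),
               "zero")
  low <- transform(recs, cattle = 0, sheep = c(1, 2, 1))
  expect_error(score_grazing(low, ct, g), "Rescale")
})

test_that("night-light quantile grading follows the rank rule", {
  g <- grid_spec(0, 1000, 1000, 1, 10, crs_id = "synthetic:laea")
  vals <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  s <- score_nightlight(raster_layer(g, vals))
  expect_equal(s$raster$values[1, ], rank(vals))  # distinct values: bins 1..10
  expect_equal(s$raster$values[1, which.min(vals)], 1)
  expect_equal(s$raster$values[1, which.max(vals)], 10)

  const <- score_nightlight(raster_layer(g, rep(3, 10)))
  expect_true(all(const$raster$values == 1))      # total tie -> lowest bin

  expect_error(score_nightlight(raster_layer(tiny_grid(2, 2), rep(1, 4))),
               "4 unmasked cells")

  # brute-force agreement on random rasters up to 1000 cells
  set.seed(2)
  for (n in c(37, 250, 1000)) {
    gg <- grid_spec(0, 1000, 1000, 1, n, crs_id = "synthetic:laea")
    v <- sample(round(rexp(n) * 20))
    got <- score_nightlight(raster_layer(gg, v))$raster$values[1, ]
    brute <- ceiling(rank(v, ties.method = "min") * 10 / n)
    expect_equal(got, pmax(1, pmin(10, brute)))
  }
})

test_that("land-use points match the published scheme", {
  g <- grid_spec(0, 1000, 1000, 1, 6, crs_id = "synthetic:laea")
  lv <- c("construction", "arable", "forest", "irrigation", "grassland", "other")
  r <- raster_layer(g, 1:6)
  attr(r, "levels") <- lv
  s <- score_landuse(r)
  expect_equal(s$raster$values[1, ], c(10, 7, 3, 3, 1, 0))

  r2 <- raster_layer(g, rep(1, 6))
  attr(r2, "levels") <- "swamp"
  expect_error(score_landuse(r2), "swamp")
})

test_that("HI composition is an equal-weight sum with intersection mask", {
  g <- tiny_grid(2, 2)
  mk <- function(v, nm) score_layer(raster_layer(g, v), nm)
  hi <- compose_hi(mk(c(0, 10, 10, 0), "population"),
                   mk(c(0, 10, 5, 0), "grazing"),
                   mk(c(0, 10, 2, 0), "access"),
                   mk(c(1, 10, 3, 1), "nightlight"),
                   mk(c(0, 10, 7, 0), "landuse"))
  expect_equal(hi$values[1, 1], 1)    # all indexes at their minima
  expect_equal(hi$values[1, 2], 50)   # all at maxima
  expect_equal(hi$values[2, 1], 27)   # 10 + 5 + 2 + 3 + 7

  # permutation invariance in the layer arguments (named)
  hi2 <- compose_hi(landuse = mk(c(0, 10, 7, 0), "landuse"),
                    nightlight = mk(c(1, 10, 3, 1), "nightlight"),
                    access = mk(c(0, 10, 2, 0), "access"),
                    grazing = mk(c(0, 10, 5, 0), "grazing"),
                    population = mk(c(0, 10, 10, 0), "population"))
  expect_identical(hi$values, hi2$values)

  # masked input cell masks the sum
  pop <- score_layer(raster_layer(g, c(NA, 0, 0, 0)), "population")
  hi3 <- compose_hi(pop, mk(c(0, 0, 0, 0), "grazing"), mk(c(0, 0, 0, 0), "access"),
                    mk(c(1, 1, 1, 1), "nightlight"), mk(c(0, 0, 0, 0), "landuse"))
  expect_false(hi3$mask[1, 1])
  expect_error(compose_hi(pop, pop, pop, pop, pop), "grazing")
})

test_that("index layers respect their bounds on random inputs", {
  g <- tiny_grid(6)
  set.seed(4)
  for (i in 1:5) {
    d <- raster_layer(g, rexp(36) * 10^runif(1, 0, 4))
    s <- score_population(d)
    v <- s$raster$values[s$raster$mask]
    expect_true(all(v >= 0 & v <= 10))
    nl <- score_nightlight(raster_layer(g, rexp(36)))
    vn <- nl$raster$values[nl$raster$mask]
    expect_true(all(vn >= 1 & vn <= 10))
  }
})
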