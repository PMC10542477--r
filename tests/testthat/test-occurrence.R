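test_that("life-form classification partitions records exactly", {
  g <- tiny_grid(10)
  occ <- rbind(make_occ(g, 1:5, "terrestrial"),
               make_occ(g, 6:8, "epiphytic"),
               make_occ(g, 9:10, "mycoheterotrophic"))
  sets <- classify_lifeform(occ)
  expect_equal(vapply(sets, nrow, 1L), c(all = 10L, t = 5L, e = 3L, m = 2L))
  expect_equal(nrow(sets$t) + nrow(sets$e) + nrow(sets$m), nrow(sets$all))
  # pairwise disjoint by construction of the label split
  expect_length(intersect(rownames(sets$t), rownames(sets$e)), 0)

  empty <- classify_lifeform(occ[0, ])
  expect_true(all(vapply(empty, nrow, 1L) == 0))

  bad <- occ
  bad$lifeform[1] <- "lithophytic"
  bad$taxon[1] <- "odd_taxon"
  expect_error(classify_lifeform(bad), "lithophytic")
  expect_error(classify_lifeform(bad), "odd_taxon")
})

test_that("thinning keeps one record per occupied cell and is idempotent", {
  g <- tiny_grid(5)
  two <- make_occ(g, c(7, 7))
  expect_equal(nrow(thin_occurrences(two, g)), 1)

  distinct <- make_occ(g, c(1, 5, 9))
  expect_equal(nrow(thin_occurrences(distinct, g)), 3)

  set.seed(3)
  cells <- sample(25, 100, replace = TRUE)
  occ <- make_occ(g, cells)
  th <- thin_occurrences(occ, g)
  expect_equal(nrow(th), length(unique(cells)))      # cell-occupancy oracle
  expect_setequal(th$cell, unique(cells))
  th2 <- thin_occurrences(th, g)
  expect_equal(th2$cell, th$cell)                    # idempotent
  # kept record is the first one seen in each cell
  expect_equal(th$taxon, occ$taxon[!duplicated(cells)])
})

test_that("pseudo-absence sampling is exclusive, sized, and seeded", {
  g <- grid_spec(0, 200 * 1000, 1000, 200, 200, crs_id = "synthetic:laea")
  pres <- sample(n_cells(g), 300)
  pa <- sample_pseudo_absence(g, pres, n = 2000, n_sets = 3, seed = 5)
  expect_length(pa, 3)
  expect_true(all(vapply(pa, length, 1L) == 2000))
  expect_true(all(vapply(pa, function(s) length(intersect(s, pres)), 1L) == 0))
  expect_true(all(vapply(pa, anyDuplicated, 1L) == 0))
  pa2 <- sample_pseudo_absence(g, pres, n = 2000, n_sets = 3, seed = 5)
  expect_identical(pa, pa2)
  pa3 <- sample_pseudo_absence(g, pres, n = 2000, n_sets = 3, seed = 6)
  expect_false(identical(pa, pa3))

  small <- tiny_grid(3)
  expect_error(sample_pseudo_absence(small, 1:5, n = 6, seed = 1), "candidate")
})

test_that("pseudo-absence draws are uniform over candidate cells", {
  g <- tiny_grid(6)  # 36 cells, 4 presences, draw 8 per replicate
  pres <- c(1, 2, 3, 4)
  counts <- integer(36)
  for (s in 1:200) {
    pa <- sample_pseudo_absence(g, pres, n = 8, n_sets = 1, seed = s)[[1]]
    counts[pa] <- counts[pa] + 1
  }
  cand <- setdiff(1:36, pres)
  p <- chisq.test(counts[cand], p = rep(1 / length(cand), length(cand)))$p.value
  expect_gt(p, 0.01)
  expect_true(all(counts[pres] == 0))
})

test_that("train/test splits are stratified, disjoint and exhaustive", {
  y <- rep(c(0, 1), each = 100)
  sp <- split_train_test(y, fraction = 0.7, n_repeats = 5, seed = 2)
  expect_length(sp, 5)
  for (s in sp) {
    expect_equal(sum(y[s$train] == 1), 70)
    expect_equal(sum(y[s$train] == 0), 70)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(y))
  }
  expect_gt(length(unique(vapply(sp, function(s) paste(s$train, collapse = ","), ""))), 1)

  # brute-force set algebra on a 20-record toy set
  y20 <- rep(c(0, 1), 10)
  sp20 <- split_train_test(y20, seed = 1)[[1]]
  expect_identical(sort(union(sp20$train, sp20$test)), 1:20)
  expect_identical(intersect(sp20$train, sp20$test), integer(0))

  expect_error(split_train_test(c(0, 1, 1, 1)), "at least 10")
  expect_error(split_train_test(c(rep(1, 11), 0)), "2 members")
})

test_that("collinearity filter drops offenders greedily at |r| >= 0.7", {
  g <- tiny_grid(100)
  set.seed(8)
  a <- rnorm(1e4)
  st <- predictor_stack(list(A = rl(g, a), B = rl(g, a),
                             C = rl(g, rnorm(1e4))))
  kept <- filter_collinear(st)
  expect_length(kept$layers, 2)            # one of the identical pair dropped
  expect_length(attr(kept, "dropped"), 1)
  expect_true(attr(kept, "dropped") %in% c("A", "B"))

  st2 <- predictor_stack(list(A = rl(g, rnorm(1e4)), B = rl(g, rnorm(1e4)),
                              C = rl(g, rnorm(1e4))))
  expect_length(filter_collinear(st2)$layers, 3)  # independent layers survive

  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(1e4)      # r(A,B) ~ 0.9
  st3 <- predictor_stack(list(A = rl(g, a), B = rl(g, b), C = rl(g, rnorm(1e4))))
  k3 <- filter_collinear(st3)
  expect_length(attr(k3, "dropped"), 1)
  expect_true(attr(k3, "dropped") %in% c("A", "B"))
  # retained pairs all below the threshold
  m <- sapply(k3$layers, function(x) as.vector(t(x$values)))
  expect_lt(max(abs(cor(m)[lower.tri(cor(m))])), 0.7)

  expect_warning(filter_collinear(predictor_stack(list(A = rl(g, a)))), "fewer")
})

test_that("prepare_datasets wires thinning and per-dataset pseudo-absences", {
  L <- small_landscape()
  occ <- rbind(make_occ(L$grid, sample(3600, 80), "terrestrial"),
               make_occ(L$grid, sample(3600, 30), "epiphytic"),
               make_occ(L$grid, sample(3600, 40), "mycoheterotrophic"))
  ds <- prepare_datasets(occ, L$grid, n_pa = 300, n_pa_sets = 2, seed = 4)
  expect_named(ds, c("all", "t", "e", "m"))
  for (d in ds) {
    expect_length(d$pa_sets, 2)
    for (s in d$pa_sets) {
      expect_length(s, 300)
      expect_length(intersect(s, d$presence_cells), 0)
    }
  }
  expect_lte(length(ds$all$presence_cells),
             length(ds$t$presence_cells) + length(ds$e$presence_cells) +
               length(ds$m$presence_cells))
})
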