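make_stack <- function(g, ...) predictor_stack(list(...))

test_that("feature building: z-scores, one-hot, interaction and quadratic counts", {
  g <- tiny_grid(10)
  set.seed(1)
  st <- predictor_stack(list(x1 = rl(g, rnorm(100)), x2 = rl(g, rnorm(100))))
  ft <- build_features(st, 1:100, algorithm = "glm")
  # 2 mains + 2 quadratics + C(2,2) = 1 pairwise interaction
  expect_equal(colnames(ft$X), c("x1", "x2", "x1^2", "x2^2", "x1:x2"))
  expect_equal(unname(colMeans(ft$X[, 1:2])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ft$X[, 1:2], 2, sd)), c(1, 1))

  st4 <- predictor_stack(list(a = rl(g, rnorm(100)), b = rl(g, rnorm(100)),
                              c = rl(g, rnorm(100)), d = rl(g, rnorm(100))))
  ft4 <- build_features(st4, 1:100, algorithm = "glm")
  expect_equal(ncol(ft4$X), 4 + 4 + choose(4, 2))       # 6 interaction columns

  stc <- predictor_stack(list(x = rl(g, rnorm(100)),
                              veg = rl(g, sample(3, 100, TRUE))),
                         categorical = list(veg = c("f", "g", "h")))
  ftc <- build_features(stc, 1:100, algorithm = "rf")
  onehot <- ftc$X[, c("veg=f", "veg=g", "veg=h")]
  expect_true(all(rowSums(onehot) == 1))
  # same-categorical indicator pairs are excluded from interactions
  ftg <- build_features(stc, 1:100, algorithm = "glm")
  expect_false(any(grepl("veg=.*:veg=", colnames(ftg$X))))

  ftm <- build_features(st, 1:100, algorithm = "maxent")
  expect_true(all(c("x1^2", "x2^2") %in% colnames(ftm$X)))

  # predict-time features reuse training statistics
  ft2 <- build_features(st, 1:50, algorithm = "glm", stats = ft$stats)
  expect_identical(ft2$stats, ft$stats)
})

test_that("penalized GLM separates separable data and recovers known coefficients", {
  g <- grid_spec(0, 1000, 1000, 1, 400, crs_id = "synthetic:laea")
  x <- c(seq(-2, -0.1, length.out = 200), seq(0.1, 2, length.out = 200))
  st <- predictor_stack(list(x = rl(g, x)))
  y <- as.integer(x > 0)
  ft <- build_features(st, 1:400, algorithm = "glm")
  fit <- fit_glm(ft$X, y)
  expect_equal(auc_score(predict_model(fit, ft$X), y), 1.0)

  set.seed(2)
  n <- 5000
  xs <- rnorm(n)
  ys <- rbinom(n, 1, plogis(1 + 2 * xs))
  X <- cbind(x = xs)
  fit2 <- fit_glm(X, ys)
  expect_equal(unname(fit2$beta), c(1, 2), tolerance = 0.15)

  yp <- sample(ys)
  fit3 <- fit_glm(X, yp)
  expect_equal(auc_score(predict_model(fit3, X), yp), 0.5, tolerance = 0.05)

  expect_error(fit_glm(X, rep(1, n)), "both classes")
})

test_that("random forest fits nonlinear structure, deterministically under seed", {
  set.seed(5)
  n <- 400
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(a, b))
  X <- cbind(a = a + rnorm(n, 0, 0.05), b = b + rnorm(n, 0, 0.05))
  fit <- fit_rf(X, y, model_spec("rf", seed = 3))
  p <- predict_model(fit, X)
  expect_gt(auc_score(p, y), 0.95)   # XOR is invisible to a main-effects GLM
  expect_true(all(p >= 0 & p <= 1))
  fit2 <- fit_rf(X, y, model_spec("rf", seed = 3))
  expect_identical(predict_model(fit2, X), p)
  expect_error(fit_rf(X, rep(1, n)), "both classes")
})

test_that("maxent-style model: monotone response, flat null, stable to background size", {
  g <- tiny_grid(60)
  set.seed(6)
  v <- rnorm(3600)
  st <- predictor_stack(list(x = rl(g, v), z = rl(g, rnorm(3600))))
  pres <- order(v, decreasing = TRUE)[1:150]   # presences at high x
  bg <- sample(3600, 1000)
  ftp <- build_features(st, pres, algorithm = "maxent")
  ftb <- build_features(st, bg, algorithm = "maxent", stats = ftp$stats)
  fit <- fit_maxent(ftp$X, ftb$X)
  # fitted response increases in x over the data range
  grid_x <- cbind(x = seq(-2, 2, length.out = 50), z = 0,
                  `x^2` = seq(-2, 2, length.out = 50)^2, `z^2` = 0)
  colnames(grid_x) <- colnames(ftp$X)
  resp <- predict_model(fit, grid_x)
  expect_gt(cor(seq(-2, 2, length.out = 50), resp, method = "spearman"), 0.9)

  # zero-signal data: near-uniform suitability
  p0 <- sample(3600, 300); b0 <- sample(3600, 1000)
  ft0p <- build_features(st, p0, algorithm = "maxent")
  ft0b <- build_features(st, b0, algorithm = "maxent", stats = ft0p$stats)
  fit0 <- fit_maxent(ft0p$X, ft0b$X)
  all_ft <- build_features(st, 1:3600, algorithm = "maxent", stats = ft0p$stats)
  expect_lt(sd(predict_model(fit0, all_ft$X)), 0.05)

  # doubling the background barely changes the cell ranking
  bg2 <- c(bg, sample(3600, 1000))
  ftb2 <- build_features(st, bg2, algorithm = "maxent", stats = ftp$stats)
  fit2 <- fit_maxent(ftp$X, ftb2$X)
  r1 <- predict_model(fit, all_ft$X); r2 <- predict_model(fit2, all_ft$X)
  expect_gt(cor(r1, r2, method = "spearman"), 0.98)

  expect_error(fit_maxent(ftp$X, ftp$X[0, , drop = FALSE]), "empty")
  expect_warning(fit_maxent(ftp$X, ftb$X[1:10, , drop = FALSE]), "smaller")
})

test_that("suitability rasters honor masks, schemas and the committee-mean bound", {
  g <- tiny_grid(6)
  vals <- rep(2, 36); vals[1] <- NA
  st <- predictor_stack(list(x = raster_layer(g, vals),
                             w = raster_layer(g, c(NA, rnorm(35)))))
  cells <- which(hisdm:::stack_mask(st))
  y <- rep(c(0, 1), length.out = length(cells))
  ft <- build_features(st, cells, algorithm = "glm")
  fit <- fit_glm(ft$X, y)
  fit$stats <- ft$stats; fit$schema <- ft$schema
  sm <- predict_suitability(fit, st)
  expect_false(sm$mask[1, 1])                 # masked stays masked
  expect_true(all(sm$values[sm$mask] >= 0 & sm$values[sm$mask] <= 1))

  # constant-predictor landscape -> constant suitability
  stc <- predictor_stack(list(x = rl(g, rep(1, 36)), w = rl(g, rep(4, 36))))
  ftc <- build_features(stc, 1:36, algorithm = "glm")
  fitc <- fit_glm(ftc$X, rep(c(0, 1), 18))
  fitc$stats <- ftc$stats; fitc$schema <- ftc$schema
  smc <- predict_suitability(fitc, stc)
  expect_equal(length(unique(round(smc$values[smc$mask], 12))), 1)

  # schema mismatch errors, naming the missing layer
  st_missing <- predictor_stack(list(x = raster_layer(g, vals)))
  expect_error(predict_suitability(fit, st_missing), "w")

  # committee mean lies between member predictions cell-wise
  p1 <- runif(36); p2 <- runif(36)
  cm <- (p1 + p2) / 2
  expect_true(all(cm >= pmin(p1, p2) & cm <= pmax(p1, p2)))
})

test_that("permutation importance isolates the generating predictor", {
  g <- tiny_grid(40)
  set.seed(9)
  x <- rnorm(1600); noise <- rnorm(1600)
  st <- predictor_stack(list(signal = rl(g, x), noise = rl(g, noise)))
  cells <- 1:1600
  y <- rbinom(1600, 1, plogis(3 * scale(x)))
  ft <- build_features(st, cells, algorithm = "glm")
  fit <- fit_glm(ft$X, y)
  fit$schema <- ft$schema
  vi <- variable_importance(fit, ft$X, y, seed = 1, n_perm = 10)
  expect_equal(vi$predictor[1], "signal")
  expect_lt(abs(vi$importance[vi$predictor == "noise"]), 0.02)

  # rank-stable across permutation seeds at higher n_perm
  v1 <- variable_importance(fit, ft$X, y, seed = 11, n_perm = 50)
  v2 <- variable_importance(fit, ft$X, y, seed = 22, n_perm = 50)
  expect_identical(v1$predictor, v2$predictor)
})
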