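#' Model specification for a suitability algorithm
#'
#' Captures the per-algorithm settings used throughout: GLM interaction level
#' 1 (all pairwise products of main-effect columns), 1000-tree random forest,
#' and an L1 penalty weight for the maximum-entropy-style model. The seed
#' fixes every stochastic fit.
#'
#' @param algorithm `"glm"`, `"rf"` or `"maxent"`.
#' @param interaction_level 0 or 1 (GLM only; 1 appends pairwise products).
#' @param n_trees Number of trees (RF only; default 1000).
#' @param regularization Total L1 penalty weight (maxent only; default 1).
#' @param seed Integer seed.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("glm", "rf", "maxent"),
                       interaction_level = 1L, n_trees = 1000L,
                       regularization = 1, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(interaction_level %in% c(0L, 1L), n_trees >= 1, regularization >= 0)
  structure(list(algorithm = algorithm,
                 interaction_level = as.integer(interaction_level),
                 n_trees = as.integer(n_trees), regularization = regularization,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Build the model feature matrix for a set of cells
#'
#' Continuous predictors are z-scored with training statistics; categorical
#' predictors are one-hot encoded over their training level registry (an
#' unseen category encodes as all zeros, with a warning). For the GLM,
#' squares of the continuous columns are appended (the quadratic logit that
#' SDM platforms fit by default) and, at interaction level 1, all pairwise
#' products of main-effect columns, excluding products of two indicator
#' columns of the same categorical (structurally zero). For maxent, squares
#' of the continuous columns are appended (linear + quadratic feature
#' class).
#'
#' @param stack A `predictor_stack`.
#' @param cells Integer cell indices.
#' @param algorithm `"glm"`, `"rf"` or `"maxent"`.
#' @param stats Training feature statistics from a previous call (use the
#'   fitted model's `stats` at predict time); `NULL` to compute from these
#'   cells.
#' @param interaction_level GLM interaction level.
#' @return List with `X` (feature matrix), `schema` (column to predictor
#'   map) and `stats`.
#' @export
build_features <- function(stack, cells, algorithm = "glm", stats = NULL,
                           interaction_level = 1L) {
  cont <- setdiff(names(stack$layers), names(stack$categorical))
  cats <- names(stack$categorical)
  if (is.null(stats)) {
    stats <- list(mean = numeric(0), sd = numeric(0), levels = stack$categorical)
    for (nm in cont) {
      v <- raster_values_vec(stack$layers[[nm]])[cells]
      stats$mean[nm] <- mean(v)
      stats$sd[nm] <- stats::sd(v)
    }
  }
  cols <- list(); schema <- list()
  for (nm in cont) {
    v <- raster_values_vec(stack$layers[[nm]])[cells]
    s <- if (stats$sd[nm] > 0) (v - stats$mean[nm]) / stats$sd[nm] else rep(0, length(v))
    cols[[nm]] <- s
    schema[[nm]] <- c(nm, NA)
  }
  for (nm in cats) {
    codes <- raster_values_vec(stack$layers[[nm]])[cells]
    lv <- stats$levels[[nm]]
    labs <- lv[codes]
    if (anyNA(labs)) warning("unseen category in '", nm, "' encoded as all-zero")
    for (k in seq_along(lv)) {
      cn <- paste0(nm, "=", lv[k])
      cols[[cn]] <- as.numeric(!is.na(labs) & labs == lv[k])
      schema[[cn]] <- c(nm, NA)
    }
  }
  main_names <- names(cols)
  owner <- vapply(schema, `[`, "", 1)
  if (algorithm %in% c("glm", "maxent")) {
    for (nm in cont) {
      cn <- paste0(nm, "^2")
      cols[[cn]] <- cols[[nm]]^2
      schema[[cn]] <- c(nm, NA)
    }
  }
  if (algorithm == "glm" && interaction_level >= 1L && length(main_names) >= 2) {
    for (i in seq_len(length(main_names) - 1)) for (j in seq((i + 1), length(main_names))) {
      a <- main_names[i]; b <- main_names[j]
      if (owner[a] == owner[b] && owner[a] %in% cats) next
      cn <- paste0(a, ":", b)
      cols[[cn]] <- cols[[a]] * cols[[b]]
      schema[[cn]] <- c(owner[a], owner[b])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  sc <- data.frame(column = names(schema),
                   p1 = vapply(schema, `[`, "", 1),
                   p2 = vapply(schema, `[`, "", 2),
                   stringsAsFactors = FALSE, row.names = NULL)
  list(X = X, schema = sc, stats = stats)
}

## Damped Newton/IRLS for a binomial logit on selected columns, with a tiny
## ridge (1e-6) on non-intercept coefficients so quasi-separable data stays
## finite. Returns coefficients and the (unpenalized) deviance.
.logit_irls <- function(X1, y, ridge = 1e-6, max_iter = 500L, tol = 1e-8) {
  n <- nrow(X1); p <- ncol(X1)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + sum(pen * b^2) / 2
  }
  f <- nll(beta)
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    g <- -drop(crossprod(X1, y - mu)) / n + pen * beta
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol) {
      dev <- 2 * sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
      return(list(beta = beta, deviance = dev, iterations = it))
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * w, X1) / n + diag(pen + 1e-12, p)
    step <- solve(H, g)
    lam <- 1
    repeat {
      bnew <- beta - lam * step
      fnew <- nll(bnew)
      if (fnew <= f + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- bnew; f <- fnew
  }
  stop(sprintf("GLM did not converge in %d iterations (gradient norm %.3g)",
               max_iter, gnorm))
}

#' Fit the stepwise-selected penalized logistic GLM
#'
#' Binomial-logit fit in the convention of the usual SDM platforms: forward
#' stepwise term selection by AIC over the supplied feature columns
#' (candidates are screened each step by their Rao score statistic given the
#' current model, the best candidate is refit by damped Newton/IRLS, and
#' selection stops when AIC no longer improves), with a tiny ridge (1e-6)
#' on the non-intercept coefficients for numerical stability. Unselected
#' columns keep coefficient zero. Deterministic given its inputs;
#' convergence of each refit is declared at gradient norm 1e-8, and failure
#' to converge within 500 iterations is an error reporting the residual
#' gradient norm.
#'
#' @param X Feature matrix from [build_features()].
#' @param y 0/1 labels (both classes present).
#' @param spec A [model_spec()] with `algorithm = "glm"`.
#' @param max_terms Cap on the number of selected columns (default 60).
#' @return An object of class `sdm_fit`.
#' @export
fit_glm <- function(X, y, spec = model_spec("glm"), max_terms = 60L) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X)
  active <- integer(0)
  fit <- .logit_irls(cbind(`(Intercept)` = rep(1, n)), y)
  aic <- fit$deviance + 2
  repeat {
    if (length(active) >= min(ncol(X), max_terms)) break
    eta <- drop(cbind(1, X[, active, drop = FALSE]) %*% fit$beta)
    mu <- stats::plogis(eta)
    r <- y - mu
    w <- pmax(mu * (1 - mu), 1e-10)
    cand <- setdiff(seq_len(ncol(X)), active)
    ## Rao score statistic per candidate, orthogonalized against the intercept
    sw <- drop(crossprod(X[, cand, drop = FALSE], r))
    xw <- drop(crossprod(X[, cand, drop = FALSE] * w, rep(1, n)))
    x2w <- drop(crossprod(X[, cand, drop = FALSE]^2, w))
    denom <- pmax(x2w - xw^2 / sum(w), 1e-12)
    score <- sw^2 / denom
    j <- cand[which.max(score)]
    trial <- .logit_irls(cbind(`(Intercept)` = 1, X[, c(active, j), drop = FALSE]), y)
    trial_aic <- trial$deviance + 2 * (length(active) + 2)
    if (trial_aic >= aic - 1e-8) break
    active <- c(active, j)
    fit <- trial
    aic <- trial_aic
  }
  beta <- numeric(ncol(X) + 1L)
  beta[1] <- fit$beta[1]
  beta[active + 1L] <- fit$beta[-1]
  names(beta) <- c("(Intercept)", colnames(X))
  structure(list(algorithm = "glm", spec = spec, beta = beta,
                 selected = colnames(X)[active], aic = aic),
            class = "sdm_fit")
}

#' Fit the 1000-tree random forest
#'
#' A seeded probability forest (class-frequency averaging over fully grown
#' trees); predicted suitability is the forest's presence probability.
#'
#' @inheritParams fit_glm
#' @param spec A [model_spec()] with `algorithm = "rf"`.
#' @return An `sdm_fit`.
#' @export
fit_rf <- function(X, y, spec = model_spec("rf")) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(y = factor(y, levels = c(0, 1)), x = df,
                        num.trees = spec$n_trees, probability = TRUE,
                        seed = spec$seed, num.threads = 1)
  structure(list(algorithm = "rf", spec = spec, forest = fit,
                 feature_names = colnames(X)),
            class = "sdm_fit")
}

#' Fit the maximum-entropy-style presence-background model
#'
#' The presence-background maximum-entropy problem is fit in its equivalent
#' weighted penalized logistic form: presences (weight 1 per unit class
#' total) against the background sample, on linear + quadratic features,
#' with an L1 penalty of total weight `spec$regularization`. Class weights
#' are balanced so the null (zero-signal) model predicts ~0.5 everywhere;
#' output is the logistic suitability in [0, 1].
#'
#' @param X_presence,X_background Feature matrices from [build_features()]
#'   with `algorithm = "maxent"`.
#' @param spec A [model_spec()] with `algorithm = "maxent"`.
#' @return An `sdm_fit`.
#' @export
fit_maxent <- function(X_presence, X_background, spec = model_spec("maxent")) {
  np <- nrow(X_presence); nb <- nrow(X_background)
  if (nb == 0) stop("empty background sample")
  if (nb < np) warning("background sample smaller than presence set")
  X <- rbind(X_presence, X_background)
  y <- c(rep(1, np), rep(0, nb))
  w <- c(rep(1, np), rep(np / nb, nb))
  dummy <- FALSE
  if (ncol(X) < 2) {  # glmnet needs >= 2 columns
    X <- cbind(X, `(dummy)` = 0)
    dummy <- TRUE
  }
  n <- length(y)
  fit <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                        lambda = spec$regularization / n, standardize = TRUE)
  b <- as.numeric(stats::coef(fit))
  structure(list(algorithm = "maxent", spec = spec,
                 a0 = b[1], beta = b[-1][seq_len(ncol(X) - dummy)],
                 feature_names = colnames(X)[seq_len(ncol(X) - dummy)]),
            class = "sdm_fit")
}

#' Dispatch a fit over the three algorithms
#'
#' @param X Feature matrix built with the matching `algorithm`.
#' @param y 0/1 labels (for maxent, 1 = presence, 0 = background).
#' @param spec A [model_spec()].
#' @return An `sdm_fit`.
#' @export
fit_sdm <- function(X, y, spec) {
  switch(spec$algorithm,
         glm = fit_glm(X, y, spec),
         rf = fit_rf(X, y, spec),
         maxent = fit_maxent(X[y == 1, , drop = FALSE], X[y == 0, , drop = FALSE], spec),
         stop("unknown algorithm: ", spec$algorithm))
}

#' Predict suitability for a feature matrix
#'
#' Uniform predict contract across algorithms: values in `[0, 1]`.
#'
#' @param fit An `sdm_fit`.
#' @param X Feature matrix with the fit's feature schema.
#' @return Numeric vector of suitabilities.
#' @export
predict_model <- function(fit, X) {
  out <- switch(fit$algorithm,
    glm = stats::plogis(drop(cbind(1, X) %*% fit$beta)),
    rf = {
      if (!identical(colnames(X), fit$feature_names)) {
        stop("feature schema mismatch; missing: ",
             paste(setdiff(fit$feature_names, colnames(X)), collapse = ", "))
      }
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      predict(fit$forest, df, num.threads = 1)$predictions[, "1"]
    },
    maxent = {
      if (!identical(colnames(X), fit$feature_names)) {
        stop("feature schema mismatch; missing: ",
             paste(setdiff(fit$feature_names, colnames(X)), collapse = ", "))
      }
      stats::plogis(fit$a0 + drop(X %*% fit$beta))
    })
  pmin(1, pmax(0, out))
}

#' Predict a suitability raster over a predictor stack
#'
#' Builds features for every valid cell with the training statistics stored
#' on the fitted run and predicts; masked cells stay masked.
#'
#' @param fit An `sdm_fit` carrying `stats` and `schema` (as attached by
#'   [fit_run()] or manually).
#' @param stack A `predictor_stack` supplying every schema layer.
#' @return A `raster_layer` of suitability in `[0, 1]`.
#' @export
predict_suitability <- function(fit, stack) {
  if (is.null(fit$stats)) stop("fit carries no feature statistics")
  need <- unique(stats::na.omit(c(fit$schema$p1, fit$schema$p2)))
  missing <- setdiff(need, names(stack$layers))
  if (length(missing)) {
    stop("stack is missing schema layers: ", paste(missing, collapse = ", "))
  }
  cells <- which(stack_mask(stack))
  ft <- build_features(stack, cells, algorithm = fit$algorithm, stats = fit$stats,
                       interaction_level = fit$spec$interaction_level)
  p <- predict_model(fit, ft$X)
  vals <- rep(NA_real_, n_cells(stack$grid))
  vals[cells] <- p
  raster_layer(stack$grid, vals, matrix(!is.na(vals), stack$grid$n_rows,
                                        stack$grid$n_cols, byrow = TRUE))
}

#' Permutation variable importance
#'
#' Importance of a predictor is the mean drop in AUC over `n_perm`
#' permutations when all feature columns derived from it (its main effect,
#' one-hot indicators, squares and interactions) are jointly permuted on
#' held-out data.
#'
#' @param fit An `sdm_fit`.
#' @param X Held-out feature matrix (schema of the fit).
#' @param y Held-out 0/1 labels.
#' @param schema Schema data frame from [build_features()] (defaults to the
#'   one stored on the fit).
#' @param seed Integer seed.
#' @param n_perm Permutations per predictor (default 10).
#' @return Data frame (`predictor`, `importance`) sorted by decreasing
#'   importance.
#' @export
variable_importance <- function(fit, X, y, schema = fit$schema, seed = 1L,
                                n_perm = 10L) {
  if (is.null(schema)) stop("no feature schema available")
  set.seed(seed)
  base <- auc_score(predict_model(fit, X), y)
  preds <- unique(stats::na.omit(c(schema$p1, schema$p2)))
  imp <- numeric(length(preds)); names(imp) <- preds
  for (p in preds) {
    colsel <- schema$column[(!is.na(schema$p1) & schema$p1 == p) |
                              (!is.na(schema$p2) & schema$p2 == p)]
    drops <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      Xp <- X
      perm <- sample.int(nrow(X))
      Xp[, colsel] <- X[perm, colsel, drop = FALSE]
      drops[k] <- base - auc_score(predict_model(fit, Xp), y)
    }
    imp[p] <- mean(drops)
  }
  out <- data.frame(predictor = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}
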