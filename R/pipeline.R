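#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

#' Derive a stage seed from the master seed
#'
#' Stage-level reproducibility without seed collisions: an FNV-style hash of
#' the stage name is mixed with the master seed and folded into `[1, 2^31-2]`.
#'
#' @param master Integer master seed.
#' @param stage Stage name string.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- 2166136261
  for (b in utf8ToInt(stage)) {
    h <- (bitwXor(h %% 2147483647, b) * 16777619) %% 2147483647
  }
  as.integer((h + (master %% 2147483647) * 69069) %% 2147483646 + 1)
}

#' Strategy label for a dataset/algorithm/HI combination
#'
#' Renders the conventional short labels: `G`, `M`, `R` for GLM, maxent and
#' random forest, joined to the dataset name (`G-all`, `R-t`, ...), with a
#' `-noHI` suffix for the HI-off condition.
#'
#' @param dataset One of `"all"`, `"t"`, `"e"`, `"m"`.
#' @param algorithm One of `"glm"`, `"maxent"`, `"rf"`.
#' @param hi_on Logical.
#' @return Character label.
#' @export
strategy_label <- function(dataset, algorithm, hi_on = TRUE) {
  letter <- c(glm = "G", maxent = "M", rf = "R")[algorithm]
  paste0(letter, "-", dataset, ifelse(hi_on, "", "-noHI"))
}

#' Parse a strategy label back to its components
#' @param label Label from [strategy_label()].
#' @return List with `dataset`, `algorithm`, `hi_on`.
#' @export
parse_strategy_label <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  alg <- c(G = "glm", M = "maxent", R = "rf")[parts[1]]
  list(dataset = parts[2], algorithm = unname(alg),
       hi_on = !(length(parts) > 2 && parts[3] == "noHI"))
}

#' Full pipeline run configuration
#'
#' @param landscape A [landscape_params()] object.
#' @param niches Named list of [niche_params()] (default [niche_presets()]).
#' @param n_pa Pseudo-absences per set (default 2000).
#' @param n_pa_sets Pseudo-absence replicate sets (default 3).
#' @param train_fraction Training fraction per split (default 0.7).
#' @param n_repeats Splits per pseudo-absence set (default 5).
#' @param algorithms Algorithms to run.
#' @param datasets Datasets to run.
#' @param hi HI conditions to run (`TRUE`, `FALSE` or both).
#' @param threshold Binarization threshold (default 0.5).
#' @param ranking A [ranking_config()].
#' @param hi_cfg An [hi_config()].
#' @param make_maps Build committee-mean suitability maps and the downstream
#'   overlay/ranking products?
#' @param seed Master seed; every stage seed is derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(landscape = landscape_params(),
                       niches = niche_presets(),
                       n_pa = 2000L, n_pa_sets = 3L,
                       train_fraction = 0.7, n_repeats = 5L,
                       algorithms = c("glm", "rf", "maxent"),
                       datasets = c("all", "t", "e", "m"),
                       hi = c(TRUE, FALSE),
                       threshold = 0.5,
                       ranking = ranking_config(),
                       hi_cfg = hi_config(),
                       make_maps = TRUE,
                       seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1,
            n_pa_sets >= 1, all(algorithms %in% c("glm", "rf", "maxent")),
            all(datasets %in% c("all", "t", "e", "m")), is.logical(hi))
  structure(list(landscape = landscape, niches = niches, n_pa = as.integer(n_pa),
                 n_pa_sets = as.integer(n_pa_sets),
                 train_fraction = train_fraction, n_repeats = as.integer(n_repeats),
                 algorithms = algorithms, datasets = datasets, hi = hi,
                 threshold = threshold, ranking = ranking, hi_cfg = hi_cfg,
                 make_maps = isTRUE(make_maps), seed = as.integer(seed)),
            class = "run_config")
}

#' Fit and evaluate one modeling run
#'
#' One run is a (dataset, pseudo-absence set, split, algorithm, HI) cell of
#' the run matrix: features are built on the training cells (training
#' z-scoring statistics), the model is fitted, and held-out metrics are
#' computed on the test cells.
#'
#' @param stack A `predictor_stack`.
#' @param presence_cells,pa_cells Integer cell indices.
#' @param split A `list(train, test)` of indices into
#'   `c(presence_cells, pa_cells)`.
#' @param spec A [model_spec()].
#' @return List with `fit` (an `sdm_fit` carrying `stats`/`schema`) and
#'   `metrics` (one-row data frame from [evaluate_run()]).
#' @export
fit_run <- function(stack, presence_cells, pa_cells, split, spec) {
  cells <- c(presence_cells, pa_cells)
  y <- c(rep(1L, length(presence_cells)), rep(0L, length(pa_cells)))
  tr <- build_features(stack, cells[split$train], algorithm = spec$algorithm,
                       interaction_level = spec$interaction_level)
  fit <- fit_sdm(tr$X, y[split$train], spec)
  fit$stats <- tr$stats
  fit$schema <- tr$schema
  te <- build_features(stack, cells[split$test], algorithm = spec$algorithm,
                       stats = tr$stats, interaction_level = spec$interaction_level)
  metrics <- evaluate_run(predict_model(fit, te$X), y[split$test])
  list(fit = fit, metrics = metrics)
}

#' Run the full fit/evaluate matrix
#'
#' Loops datasets x algorithms x HI conditions x pseudo-absence sets x
#' splits, returning a per-run metrics table and (optionally) the
#' committee-mean suitability raster per strategy (the mean of the
#' per-run suitability maps over the `n_pa_sets * n_repeats` runs).
#'
#' @param stacks Named list with elements `"TRUE"` and/or `"FALSE"`: the
#'   filtered predictor stack for each HI condition.
#' @param datasets Named list of `model_dataset`s.
#' @param config A [run_config()].
#' @param make_maps Override `config$make_maps`.
#' @return List with `metrics` (data frame, one row per run) and `maps`
#'   (named list of committee-mean `raster_layer`s by strategy label, or
#'   `NULL`).
#' @export
run_matrix <- function(stacks, datasets, config, make_maps = config$make_maps) {
  metrics <- list(); maps <- list(); map_runs <- list()
  for (hi_on in config$hi) {
    stack <- stacks[[as.character(hi_on)]]
    for (ds_name in config$datasets) {
      ds <- datasets[[ds_name]]
      if (is.null(ds)) next
      cells_all <- c(ds$presence_cells)
      split_seed <- derive_seed(config$seed, paste0("split:", ds_name))
      for (ps in seq_len(config$n_pa_sets)) {
        pa <- ds$pa_sets[[ps]]
        y <- c(rep(1L, length(ds$presence_cells)), rep(0L, length(pa)))
        splits <- split_train_test(y, fraction = config$train_fraction,
                                  n_repeats = config$n_repeats,
                                  seed = split_seed + ps)
        for (rp in seq_len(config$n_repeats)) {
          for (alg in config$algorithms) {
            spec <- model_spec(alg, seed = derive_seed(config$seed,
                                                       paste(alg, ds_name, hi_on, ps, rp)))
            run <- fit_run(stack, ds$presence_cells, pa, splits[[rp]], spec)
            lbl <- strategy_label(ds_name, alg, hi_on)
            metrics[[length(metrics) + 1L]] <-
              data.frame(strategy = lbl, dataset = ds_name, algorithm = alg,
                         hi_on = hi_on, pa_set = ps, rep = rp, run$metrics,
                         stringsAsFactors = FALSE)
            if (make_maps) {
              sm <- predict_suitability(run$fit, stack)
              if (is.null(maps[[lbl]])) {
                maps[[lbl]] <- raster_values_vec(sm)
                map_runs[[lbl]] <- 1L
              } else {
                maps[[lbl]] <- maps[[lbl]] + raster_values_vec(sm)
                map_runs[[lbl]] <- map_runs[[lbl]] + 1L
              }
            }
          }
        }
      }
    }
  }
  grid <- stacks[[1]]$grid
  committee <- NULL
  if (make_maps && length(maps)) {
    committee <- lapply(names(maps), function(lbl) {
      raster_layer(grid, maps[[lbl]] / map_runs[[lbl]])
    })
    names(committee) <- names(maps)
  }
  list(metrics = do.call(rbind, metrics), maps = committee)
}

#' Paired strategy comparisons for a metrics table
#'
#' Builds the two published comparison families: life-form classification
#' strategies against the pooled all-data strategy (per algorithm and HI
#' condition), and HI-on against HI-off (per dataset and algorithm), each
#' tested separately per metric with a paired t-test over the shared
#' (pseudo-absence set, split) run labels.
#'
#' @param metrics Metrics table from [run_matrix()].
#' @param alpha Significance level (default 0.05).
#' @param metric_cols Metric columns to test.
#' @return Data frame of comparison rows.
#' @export
strategy_comparisons <- function(metrics, alpha = 0.05,
                                 metric_cols = c("auc", "tss", "kappa")) {
  out <- list()
  pick <- function(d, a, h) metrics[metrics$dataset == d & metrics$algorithm == a &
                                      metrics$hi_on == h, , drop = FALSE]
  for (a in unique(metrics$algorithm)) for (h in unique(metrics$hi_on)) {
    base <- pick("all", a, h)
    if (!nrow(base)) next
    for (d in setdiff(unique(metrics$dataset), "all")) {
      cls <- pick(d, a, h)
      if (!nrow(cls)) next
      for (mc in metric_cols) {
        cmp <- compare_strategies(cls, base, metric = mc, alpha = alpha)
        out[[length(out) + 1L]] <-
          data.frame(family = "classification_vs_all",
                     group_a = strategy_label(d, a, h),
                     group_b = strategy_label("all", a, h), cmp,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (all(c(TRUE, FALSE) %in% unique(metrics$hi_on))) {
    for (a in unique(metrics$algorithm)) for (d in unique(metrics$dataset)) {
      on <- pick(d, a, TRUE); off <- pick(d, a, FALSE)
      if (!nrow(on) || !nrow(off)) next
      for (mc in metric_cols) {
        cmp <- compare_strategies(on, off, metric = mc, alpha = alpha)
        out[[length(out) + 1L]] <-
          data.frame(family = "hi_vs_nohi",
                     group_a = strategy_label(d, a, TRUE),
                     group_b = strategy_label(d, a, FALSE), cmp,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- (bitwXor(h %% 2147483647, b) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h %% 4294967L))
}

#' Run the complete analysis pipeline
#'
#' Orchestrates: synthetic landscape -> HI scoring -> occurrence generation
#' and preparation -> the fit/evaluate matrix -> paired strategy comparisons
#' -> committee-map binarization, life-form fusion and change analysis ->
#' county zonal areas -> double ranking. Fully deterministic under the
#' master seed; every stage seed derives from it via [derive_seed()].
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, metrics, comparisons,
#'   summaries, rankings and a JSON manifest are written there.
#' @return A list of class `pipeline_result` with elements `landscape`,
#'   `hi`, `stacks`, `datasets`, `metrics`, `comparisons`, `maps`,
#'   `binary_maps`, `changes`, `area_summaries`, `rankings`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  message("stage: synthetic landscape")
  ls_params <- config$landscape
  ls_params$seed <- derive_seed(config$seed, "landscape")
  landscape <- generate_landscape(ls_params)

  message("stage: human influence")
  hi <- compute_hi(landscape, cfg = config$hi_cfg)
  stacks <- list()
  for (hi_on in config$hi) {
    st <- assemble_stack(landscape, if (hi_on) hi$hi else NULL)
    stacks[[as.character(hi_on)]] <- filter_collinear(st)
  }

  message("stage: occurrences")
  occ <- do.call(rbind, lapply(names(config$niches), function(nm) {
    as.data.frame(generate_occurrences(landscape$env, config$niches[[nm]],
                                       seed = derive_seed(config$seed, paste0("occ:", nm))))
  }))
  occ <- occurrence_set(occ)

  message("stage: dataset preparation")
  valid <- which(stack_mask(stacks[[1]]))
  datasets <- prepare_datasets(occ, landscape$grid, n_pa = config$n_pa,
                               n_pa_sets = config$n_pa_sets,
                               seed = derive_seed(config$seed, "pa"),
                               valid_cells = valid)

  message("stage: fit/evaluate matrix")
  mx <- run_matrix(stacks, datasets, config)
  metrics <- mx$metrics

  message("stage: comparisons")
  comparisons <- strategy_comparisons(metrics)

  binary_maps <- changes <- area_summaries <- rankings <- NULL
  if (config$make_maps && !is.null(mx$maps)) {
    message("stage: maps and ranking")
    binary_maps <- lapply(mx$maps, binarize, threshold = config$threshold)
    assignment <- county_assignment(landscape$grid, landscape$counties)
    changes <- list()
    for (hi_on in config$hi) for (alg in config$algorithms) {
      nms <- strategy_label(c("all", "t", "e", "m"), alg, hi_on)
      if (!all(nms %in% names(binary_maps))) next
      fused <- fuse_lifeform_layers(binary_maps[[nms[2]]], binary_maps[[nms[3]]],
                                    binary_maps[[nms[4]]])
      changes[[strategy_label("all", alg, hi_on)]] <-
        changed_area(binary_maps[[nms[1]]], fused)
    }
    area_summaries <- suitable_area_summary(binary_maps, landscape$counties,
                                            assignment = assignment)
    rankings <- list()
    for (d in config$datasets) {
      labels <- metrics$strategy[metrics$dataset == d]
      labels <- unique(labels)
      labels <- labels[labels %in% area_summaries$by_county$map]
      if (!length(labels)) next
      sa <- lapply(labels, function(l) {
        bc <- area_summaries$by_county
        bc[bc$map == l, c("county_id", "area_km2"), drop = FALSE]
      })
      names(sa) <- labels
      rankings[[d]] <- double_rank(sa, config$ranking)
    }
  }

  manifest <- list(
    config_hash = .config_hash(config),
    master_seed = config$seed,
    strategies = sort(unique(metrics$strategy)),
    n_strategies = length(unique(metrics$strategy)),
    n_runs = nrow(metrics),
    n_predictors = lapply(stacks, function(s) length(s$layers)),
    dropped_collinear = lapply(stacks, function(s) attr(s, "dropped")),
    datasets = lapply(datasets, function(d)
      list(n_presence_cells = length(d$presence_cells),
           pa_set_sizes = vapply(d$pa_sets, length, 1L))))

  result <- structure(list(landscape = landscape, hi = hi, stacks = stacks,
                           datasets = datasets, metrics = metrics,
                           comparisons = comparisons, maps = mx$maps,
                           binary_maps = binary_maps, changes = changes,
                           area_summaries = area_summaries, rankings = rankings,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' Write pipeline outputs to a directory
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(result$comparisons)) {
    utils::write.csv(result$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$area_summaries)) {
    utils::write.csv(result$area_summaries$totals, file.path(dir, "area_totals.csv"),
                     row.names = FALSE)
    utils::write.csv(result$area_summaries$by_county,
                     file.path(dir, "area_by_county.csv"), row.names = FALSE)
  }
  if (!is.null(result$rankings)) {
    rows <- list()
    for (d in names(result$rankings)) {
      rk <- result$rankings[[d]]
      for (s in names(rk$per_strategy)) {
        ps <- rk$per_strategy[[s]]
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = d, strategy = s,
          county_id = ps$ranked$county_id, area_km2 = ps$ranked$area_km2,
          cum_share = ps$ranked$cum_share,
          in_sequential = ps$ranked$county_id %in% ps$sequential_set,
          in_area_weight = ps$ranked$county_id %in% ps$area_weight_set,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = d, strategy = "consensus", county_id = rk$consensus,
        area_km2 = NA_real_, cum_share = NA_real_, in_sequential = TRUE,
        in_area_weight = TRUE, stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, rows), file.path(dir, "rankings.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
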