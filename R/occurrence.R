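#' Occurrence records with life-form labels
#'
#' @param df Data frame with columns `lon`, `lat` (grid CRS coordinates),
#'   `taxon` and `lifeform` (one of `terrestrial`, `epiphytic`,
#'   `mycoheterotrophic`).
#' @return A data frame of class `occurrence_set`.
#' @export
occurrence_set <- function(df) {
  stopifnot(all(c("lon", "lat", "taxon", "lifeform") %in% names(df)))
  known <- c("terrestrial", "epiphytic", "mycoheterotrophic")
  bad <- setdiff(unique(df$lifeform), known)
  if (length(bad)) {
    stop("unknown life form label(s): ", paste(bad, collapse = ", "),
         " (offending taxa: ",
         paste(unique(df$taxon[df$lifeform %in% bad]), collapse = ", "), ")")
  }
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Read / write occurrence CSV
#' @param path CSV path with columns `lon,lat,taxon,lifeform`.
#' @return An `occurrence_set`.
#' @export
read_occurrences <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_occurrences
#' @param occ An `occurrence_set`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Split occurrences into the four analysis sets
#'
#' Partitions records by life form into `t`, `e` and `m` sets and keeps the
#' pooled set `all`; the three life-form sets are pairwise disjoint, their
#' union is `all`, and record counts are conserved.
#'
#' @param records An `occurrence_set` (every record labelled).
#' @return Named list of `occurrence_set`s: `all`, `t`, `e`, `m`.
#' @export
classify_lifeform <- function(records) {
  records <- occurrence_set(as.data.frame(records))
  list(all = records,
       t = occurrence_set(records[records$lifeform == "terrestrial", , drop = FALSE]),
       e = occurrence_set(records[records$lifeform == "epiphytic", , drop = FALSE]),
       m = occurrence_set(records[records$lifeform == "mycoheterotrophic", , drop = FALSE]))
}

#' Thin occurrences to one record per grid cell
#'
#' Implements the 1-km spatial-autocorrelation limit as one-record-per-cell
#' thinning on the analysis grid: within each occupied cell the record with
#' the lowest row index is kept, so the result has exactly one record per
#' occupied cell and the operation is idempotent.
#'
#' @param points An `occurrence_set`.
#' @param grid A `grid_spec`.
#' @return A thinned `occurrence_set` with a `cell` column appended.
#' @export
thin_occurrences <- function(points, grid) {
  df <- as.data.frame(points)
  if (nrow(df) == 0) {
    df$cell <- integer(0)
    return(occurrence_set(df))
  }
  cell <- xy_to_cell(grid, df$lon, df$lat)
  if (anyNA(cell)) stop("occurrence coordinates outside the grid extent")
  keep <- !duplicated(cell)
  out <- df[keep, , drop = FALSE]
  out$cell <- cell[keep]
  rownames(out) <- NULL
  occurrence_set(out)
}

#' Sample pseudo-absence cells
#'
#' Draws `n_sets` independent sets of `n` distinct cells uniformly at random
#' from the valid cells that are not presence cells; sets are reproducible
#' under the seed.
#'
#' @param grid A `grid_spec`.
#' @param presence_cells Integer cell indices occupied by presences.
#' @param n Pseudo-absences per set (default 2000).
#' @param n_sets Number of replicate sets (default 3).
#' @param seed Integer seed.
#' @param valid_cells Candidate cells (default: all grid cells); masked cells
#'   should be excluded by the caller.
#' @return List of `n_sets` integer vectors.
#' @export
sample_pseudo_absence <- function(grid, presence_cells, n = 2000L, n_sets = 3L,
                                  seed = 1L, valid_cells = seq_len(n_cells(grid))) {
  pool <- setdiff(valid_cells, presence_cells)
  if (length(pool) < n) {
    stop(sprintf("cannot draw %d pseudo-absences from %d candidate cells",
                 n, length(pool)))
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) sample(pool, n))
}

#' Stratified train/test splits
#'
#' Per repeat, `round(fraction * n)` records of each class go to training and
#' the rest to testing; the partitions are disjoint, exhaustive, and
#' reproducible under the seed.
#'
#' @param labels 0/1 (or logical) class labels.
#' @param fraction Training fraction (default 0.7).
#' @param n_repeats Number of repeated splits (default 5).
#' @param seed Integer seed.
#' @return List of `n_repeats` lists with integer index vectors `train` and
#'   `test`.
#' @export
split_train_test <- function(labels, fraction = 0.7, n_repeats = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(labels) < 10) stop("need at least 10 records to split")
  if (min(table(labels)) < 2) stop("every class needs at least 2 members")
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      train <- c(train, sample(idx, round(fraction * length(idx))))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Drop collinear continuous predictors
#'
#' Greedy elimination: while any pair of continuous layers has
#' `|Pearson r| >= threshold` over jointly unmasked cells, the member of the
#' worst-offending pair with the larger mean absolute correlation to all
#' remaining layers is dropped. Categorical layers are exempt. All retained
#' continuous pairs satisfy `|r| < threshold`.
#'
#' @param stack A `predictor_stack`.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return A `predictor_stack` with the surviving layers; dropped names in
#'   attribute `dropped`.
#' @export
filter_collinear <- function(stack, threshold = 0.7) {
  cont <- setdiff(names(stack$layers), names(stack$categorical))
  if (length(cont) < 2) {
    warning("fewer than 2 continuous layers; nothing to filter")
    attr(stack, "dropped") <- character(0)
    return(stack)
  }
  m <- stack_mask(stack)
  X <- vapply(cont, function(nm) raster_values_vec(stack$layers[[nm]])[m],
              numeric(sum(m)))
  R <- abs(stats::cor(X))
  diag(R) <- 0
  keep <- colnames(R)
  dropped <- character(0)
  repeat {
    sub <- R[keep, keep, drop = FALSE]
    worst <- max(sub)
    if (worst < threshold) break
    pair <- which(sub == worst, arr.ind = TRUE)[1, ]
    cand <- keep[pair]
    meanabs <- colMeans(sub[, cand, drop = FALSE])
    drop <- cand[order(-meanabs, match(cand, keep))][1]
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
  }
  retained <- names(stack$layers)[names(stack$layers) %in% c(keep, names(stack$categorical))]
  out <- predictor_stack(stack$layers[retained], categorical = stack$categorical)
  attr(out, "dropped") <- dropped
  out
}

#' Assemble a model dataset (presences plus pseudo-absence sets)
#'
#' @param name Dataset label (`"all"`, `"t"`, `"e"`, `"m"`).
#' @param presence_cells Thinned presence cell indices.
#' @param pa_sets List of pseudo-absence cell index vectors.
#' @return A list of class `model_dataset`.
#' @export
model_dataset <- function(name, presence_cells, pa_sets) {
  for (s in pa_sets) {
    if (length(intersect(presence_cells, s))) {
      stop("pseudo-absence set overlaps presence cells")
    }
  }
  structure(list(name = name, presence_cells = as.integer(presence_cells),
                 pa_sets = lapply(pa_sets, as.integer)),
            class = "model_dataset")
}

#' Prepare the four model datasets from occurrences
#'
#' Runs life-form classification, per-dataset thinning and per-dataset
#' pseudo-absence sampling (each dataset draws its own sets, excluding only
#' its own presence cells).
#'
#' @param records Pooled `occurrence_set`.
#' @param grid A `grid_spec`.
#' @param n_pa Pseudo-absences per set.
#' @param n_pa_sets Sets per dataset.
#' @param seed Integer seed.
#' @param valid_cells Candidate cells for pseudo-absences.
#' @return Named list of `model_dataset`s (`all`, `t`, `e`, `m`); datasets
#'   with no presences are dropped with a message.
#' @export
prepare_datasets <- function(records, grid, n_pa = 2000L, n_pa_sets = 3L,
                             seed = 1L, valid_cells = seq_len(n_cells(grid))) {
  sets <- classify_lifeform(records)
  out <- list()
  for (nm in names(sets)) {
    if (nrow(sets[[nm]]) == 0) {
      message("dataset '", nm, "' has no presences; skipped")
      next
    }
    thinned <- thin_occurrences(sets[[nm]], grid)
    pa <- sample_pseudo_absence(grid, thinned$cell, n = n_pa, n_sets = n_pa_sets,
                                seed = seed + match(nm, c("all", "t", "e", "m")),
                                valid_cells = valid_cells)
    out[[nm]] <- model_dataset(nm, thinned$cell, pa)
  }
  out
}
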