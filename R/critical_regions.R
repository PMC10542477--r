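#' Double-ranking configuration
#'
#' @param sequential_fraction Fraction of counties retained by the
#'   sequential-rank screen (default 0.30, "top 30%").
#' @param area_fraction Cumulative-area fraction the area-weight screen must
#'   reach (default 0.50).
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(sequential_fraction = 0.30, area_fraction = 0.50) {
  stopifnot(sequential_fraction > 0, sequential_fraction <= 1,
            area_fraction > 0, area_fraction <= 1)
  structure(list(sequential_fraction = sequential_fraction,
                 area_fraction = area_fraction),
            class = "ranking_config")
}

.sorted_areas <- function(county_areas) {
  stopifnot(all(c("county_id", "area_km2") %in% names(county_areas)))
  o <- order(-county_areas$area_km2, county_areas$county_id)
  county_areas[o, , drop = FALSE]
}

#' Sequential-rank screen: top fraction of counties by suitable area
#'
#' Counties are sorted by decreasing suitable area (ties broken by ascending
#' `county_id`) and the first `ceiling(fraction * n_counties)` are returned.
#'
#' @param county_areas Data frame with `county_id`, `area_km2`.
#' @param fraction Fraction of counties to keep (default 0.30).
#' @return Character vector of county ids (empty, with a warning, when all
#'   areas are zero).
#' @export
rank_sequential <- function(county_areas, fraction = 0.30) {
  s <- .sorted_areas(county_areas)
  if (all(s$area_km2 == 0)) {
    warning("all county areas are zero; sequential screen returns no county")
    return(character(0))
  }
  k <- ceiling(fraction * nrow(s))
  s$county_id[seq_len(k)]
}

#' Area-weight screen: smallest top prefix reaching a share of total area
#'
#' Returns the shortest prefix of the descending area sequence whose
#' cumulative area reaches `fraction` of the total suitable area.
#'
#' @inheritParams rank_sequential
#' @param fraction Cumulative-area share to reach (default 0.50).
#' @return Character vector of county ids.
#' @export
rank_area_weight <- function(county_areas, fraction = 0.50) {
  s <- .sorted_areas(county_areas)
  total <- sum(s$area_km2)
  if (total <= 0) stop("total suitable area is zero; area-weight screen undefined")
  k <- which(cumsum(s$area_km2) >= fraction * total - 1e-9)[1]
  s$county_id[seq_len(k)]
}

#' Double ranking across modeling strategies
#'
#' Applies both screens to each strategy's county areas, intersects them per
#' strategy, and intersects across strategies to get the consensus: the
#' counties at the forefront of both the sequential and the area weights no
#' matter the modeling strategy.
#'
#' @param strategy_areas Named list of per-strategy county-area data frames
#'   (`county_id`, `area_km2`).
#' @param cfg A [ranking_config()].
#' @return A list of class `ranking_result`: `per_strategy` (each with
#'   `sequential_set`, `area_weight_set`, `intersection`, and the ranked
#'   areas with cumulative shares) and `consensus`.
#' @export
double_rank <- function(strategy_areas, cfg = ranking_config()) {
  stopifnot(length(strategy_areas) >= 1, !is.null(names(strategy_areas)))
  per <- list()
  for (nm in names(strategy_areas)) {
    ca <- strategy_areas[[nm]]
    s <- .sorted_areas(ca)
    s$cum_share <- if (sum(s$area_km2) > 0) cumsum(s$area_km2) / sum(s$area_km2) else NA_real_
    seq_set <- suppressWarnings(rank_sequential(ca, cfg$sequential_fraction))
    area_set <- rank_area_weight(ca, cfg$area_fraction)
    per[[nm]] <- list(sequential_set = seq_set,
                      area_weight_set = area_set,
                      intersection = intersect(seq_set, area_set),
                      ranked = s)
  }
  consensus <- Reduce(intersect, lapply(per, `[[`, "intersection"))
  structure(list(per_strategy = per, consensus = consensus, config = cfg),
            class = "ranking_result")
}
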