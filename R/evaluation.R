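#' Rank-based AUC (Mann-Whitney with half-credit for ties)
#'
#' The probability that a randomly chosen presence is scored above a
#' randomly chosen absence, counting ties as half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) observed labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix at a threshold
#'
#' Predicted presence is `score > threshold` (strictly greater, matching the
#' binarization rule for suitability maps).
#'
#' @param tp,fp,tn,fn Cell counts (direct construction), or use `scores`,
#'   `labels`, `threshold`.
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn),
            class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param scores,labels,threshold Score/label vectors and cut-off.
#' @export
confusion_from_scores <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  confusion_matrix(tp = sum(pred == 1 & labels == 1),
                   fp = sum(pred == 1 & labels == 0),
                   tn = sum(pred == 0 & labels == 0),
                   fn = sum(pred == 0 & labels == 1))
}

#' True skill statistic: sensitivity + specificity - 1
#'
#' @param cm A `confusion_matrix`.
#' @return TSS in `[-1, 1]`.
#' @export
tss_score <- function(cm) {
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    stop("TSS undefined: an observed class margin is empty")
  }
  cm$tp / (cm$tp + cm$fn) + cm$tn / (cm$tn + cm$fp) - 1
}

#' Cohen's kappa: chance-corrected agreement
#'
#' `(observed agreement - chance agreement) / (1 - chance agreement)`, with
#' chance agreement from the marginal products. Degenerate margins (chance
#' agreement 1) return 0 with a warning.
#'
#' @param cm A `confusion_matrix`.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_score <- function(cm) {
  n <- cm$n
  if (n == 0) stop("empty confusion matrix")
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) + (cm$tn + cm$fp) * (cm$tn + cm$fn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate margins: chance agreement is 1; kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Metric-maximizing threshold
#'
#' Scans every distinct score as a cut-point (plus 0.5 and an all-presence
#' sentinel) and returns the threshold maximizing the metric; ties go to the
#' lowest threshold. The returned value is therefore never below the value
#' at a fixed 0.5.
#'
#' @param scores,labels Score/label vectors (both classes present).
#' @param metric `"tss"` or `"kappa"`.
#' @return List with `threshold` and `value`.
#' @export
best_threshold_metric <- function(scores, labels, metric = c("tss", "kappa")) {
  metric <- match.arg(metric)
  fun <- if (metric == "tss") tss_score else kappa_score
  cand <- sort(unique(c(-Inf, scores, 0.5)))
  best_t <- cand[1]; best_v <- -Inf
  for (t in cand) {
    v <- suppressWarnings(fun(confusion_from_scores(scores, labels, t)))
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  list(threshold = best_t, value = best_v)
}

#' Evaluate one run: AUC plus best-threshold and fixed-0.5 TSS/Kappa
#'
#' @param scores,labels Held-out scores and 0/1 labels.
#' @return One-row data frame with `auc`, `tss`, `kappa` (best-threshold),
#'   their thresholds, and `tss_05`, `kappa_05` at the fixed 0.5 cut.
#' @export
evaluate_run <- function(scores, labels) {
  bt <- best_threshold_metric(scores, labels, "tss")
  bk <- best_threshold_metric(scores, labels, "kappa")
  cm05 <- confusion_from_scores(scores, labels, 0.5)
  data.frame(auc = auc_score(scores, labels),
             tss = bt$value, tss_threshold = bt$threshold,
             kappa = bk$value, kappa_threshold = bk$threshold,
             tss_05 = suppressWarnings(tss_score(cm05)),
             kappa_05 = suppressWarnings(kappa_score(cm05)))
}

#' Paired comparison of two modeling strategies
#'
#' Pairs runs of two strategies by their `(pa_set, repeat)` labels and
#' applies a paired two-sided t-test to the per-run metric differences
#' (a - b). Zero-variance differences are degenerate: identical groups give
#' `t = 0, p = 1`; a constant nonzero shift is reported significant with
#' `p = 0` and a warning.
#'
#' @param results_a,results_b Data frames with columns `pa_set`, `rep` and
#'   the metric column.
#' @param metric Metric column name (default `"auc"`).
#' @param alpha Significance level (default 0.05).
#' @return A one-row data frame (class `comparison_result`): mean
#'   difference, t statistic, p value, significance flag.
#' @export
compare_strategies <- function(results_a, results_b, metric = "auc",
                               alpha = 0.05) {
  key <- function(d) paste(d$pa_set, d$rep, sep = "|")
  ka <- key(results_a); kb <- key(results_b)
  orphans <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(orphans)) {
    stop("unpairable runs: ", paste(unique(orphans), collapse = ", "))
  }
  if (length(ka) < 3) stop("need at least 3 paired runs")
  d <- results_a[[metric]][order(ka)] - results_b[[metric]][order(kb)]
  n <- length(d)
  md <- mean(d); sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      warning("zero variance in paired differences with nonzero mean; p -> 0")
      t_stat <- sign(md) * Inf; p <- 0
    }
  } else {
    t_stat <- md / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  out <- data.frame(metric = metric, n_pairs = n, mean_diff = md,
                    t_statistic = t_stat, p_value = p,
                    significant = p < alpha)
  class(out) <- c("comparison_result", "data.frame")
  out
}
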