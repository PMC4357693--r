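# Benchmarking a ranking against disease gene sets: cumulative recovery at
# percentile cutoffs, predicted-vs-annotated threshold sweeps, ROC/AUC via
# the rank-sum formulation, and hypergeometric set enrichment. Genes in a
# benchmark set that were never scored are dropped (and reported), not
# counted as misses.

match_set <- function(scores, gene_set, what) {
  inset <- intersect(gene_set, scores$unit_id)
  if (length(inset) == 0L) {
    miss <- utils::head(setdiff(gene_set, scores$unit_id), 5L)
    stop(sprintf("%s: no gene of the set is scored (unmatched e.g.: %s)",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  dropped <- length(gene_set) - length(inset)
  if (dropped > 0L)
    message(sprintf("%s: dropped %d unscored gene(s) from the set", what, dropped))
  inset
}

#' Disease-gene recovery at a percentile cutoff
#'
#' Count and percentage of the gene set found at or below (`"le"`, the
#' default, matching "within the Nth percentile") or strictly below
#' (`"lt"`) a percentile cutoff, among the set's scored members.
#'
#' @param scores an `intol_scores` data.frame.
#' @param gene_set character vector of gene ids.
#' @param cutoff percentile cutoff (default 25).
#' @param comparator `"le"` (percentile <= cutoff) or `"lt"` (strict).
#' @return list with `count`, `percent`, and `n_set` (scored set size).
#' @export
recovery_at <- function(scores, gene_set, cutoff = 25, comparator = c("le", "lt")) {
  comparator <- match.arg(comparator)
  inset <- match_set(scores, gene_set, "recovery_at")
  pct <- scores$percentile[match(inset, scores$unit_id)]
  cnt <- if (comparator == "le") sum(pct <= cutoff) else sum(pct < cutoff)
  list(count = cnt, percent = 100 * cnt / length(inset), n_set = length(inset))
}

#' Cumulative recovery curve
#'
#' [recovery_at()] evaluated over a grid of cutoffs; the curve is
#' non-decreasing and reaches 100% at cutoff 100.
#'
#' @inheritParams recovery_at
#' @param cutoffs percentile grid (default 1..100).
#' @return data.frame with `cutoff`, `count`, `recovered_pct`; attribute
#'   `n_set` gives the scored set size.
#' @export
recovery_curve <- function(scores, gene_set, cutoffs = 1:100, comparator = c("le", "lt")) {
  comparator <- match.arg(comparator)
  inset <- match_set(scores, gene_set, "recovery_curve")
  pct <- scores$percentile[match(inset, scores$unit_id)]
  cnt <- vapply(cutoffs, function(ct)
    if (comparator == "le") sum(pct <= ct) else sum(pct < ct), integer(1))
  out <- data.frame(cutoff = cutoffs, count = cnt,
                    recovered_pct = 100 * cnt / length(inset))
  attr(out, "n_set") <- length(inset)
  out
}

#' Predicted-vs-annotated sweep over percentile cutoffs
#'
#' At each cutoff: how many genes are predicted intolerant (percentile <=
#' cutoff), how many of those are annotated, and the annotated percentage
#' (`NA` when nothing is predicted).
#'
#' @param scores an `intol_scores` data.frame.
#' @param annotated character vector of annotated gene ids.
#' @param cutoffs percentile grid.
#' @return data.frame with `cutoff`, `n_predicted`, `n_annotated`,
#'   `pct_annotated`.
#' @export
threshold_sweep_annotated <- function(scores, annotated, cutoffs) {
  if (length(cutoffs) == 0L) stop("threshold_sweep_annotated: empty cutoff list", call. = FALSE)
  rows <- lapply(cutoffs, function(ct) {
    pred <- scores$unit_id[scores$percentile <= ct]
    n_ann <- length(intersect(pred, annotated))
    data.frame(cutoff = ct, n_predicted = length(pred), n_annotated = n_ann,
               pct_annotated = if (length(pred) > 0L) 100 * n_ann / length(pred) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC for a ranking against a positive gene set
#'
#' Lower percentile = predicted positive. The AUC is computed by the
#' rank-sum (Mann-Whitney) formulation with midranks for ties, i.e. the
#' probability that a random positive out-ranks a random negative.
#'
#' @param scores an `intol_scores` data.frame.
#' @param positives character vector of positive gene ids.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, positives) {
  is_pos <- scores$unit_id %in% positives
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc: need at least one positive and one negative among scored genes", call. = FALSE)
  # higher score = more positive; use negated percentile
  s <- -scores$percentile
  rk <- rank(s, ties.method = "average")
  auc <- (sum(rk[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores$percentile))
  pts <- data.frame(
    threshold = c(-Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(!is_pos & scores$percentile <= t) / n0, numeric(1))),
    tpr = c(0, vapply(thr, function(t) sum(is_pos & scores$percentile <= t) / n1, numeric(1))))
  list(points = pts, auc = auc)
}

#' Fraction of a gene set carrying an annotation
#'
#' @param members character vector (non-empty), e.g. a subnetwork's genes.
#' @param annotated character vector of annotated gene ids.
#' @return list with `count`, `percent`, `display` (integer percent, rounded
#'   half away from zero).
#' @export
annotation_fraction <- function(members, annotated) {
  members <- unique(members)
  if (length(members) == 0L) stop("annotation_fraction: empty member set", call. = FALSE)
  cnt <- length(intersect(members, annotated))
  pct <- 100 * cnt / length(members)
  list(count = cnt, percent = pct, display = as.integer(round_half_away(pct)))
}

#' Hypergeometric enrichment (upper tail)
#'
#' P(X >= k) where X counts annotated genes in a size-n set drawn without
#' replacement from a genome of N genes of which K are annotated.
#'
#' @param k observed overlap.
#' @param K annotated genes genome-wide.
#' @param n set size.
#' @param N genome size.
#' @return upper-tail p-value.
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) || K > N || n > N)
    stop("hypergeom_enrichment: need 0 <= k <= min(K, n) <= N and K, n <= N", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
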