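# Tissue/cell-type-specific re-ranking: genes not reliably expressed in a
# context (mean TPM <= threshold across the context's samples) are removed
# and percentiles are recomputed among the survivors. Studentized residuals
# are NOT refit — the context ranking is the global ranking restricted to
# expressed genes, so the relative order of any two retained genes is
# unchanged.

#' Mean expression of each gene within a context term
#'
#' Arithmetic mean TPM over the term's samples that are present in the
#' matrix.
#'
#' @param matrix genes x samples TPM matrix from [read_expression()].
#' @param grouping data.frame from [read_grouping()].
#' @param term_id context term to evaluate.
#' @return named numeric vector, gene id -> mean TPM.
#' @export
mean_expression <- function(matrix, grouping, term_id) {
  samples <- grouping$sample_id[grouping$term_id == term_id]
  if (length(samples) == 0L)
    stop(sprintf("mean_expression: term '%s' not found in grouping", term_id), call. = FALSE)
  present <- intersect(samples, colnames(matrix))
  if (length(present) == 0L)
    stop(sprintf("mean_expression: no sample of term '%s' is present in the expression matrix", term_id),
         call. = FALSE)
  rowMeans(matrix[, present, drop = FALSE])
}

#' Genes reliably expressed in a context
#'
#' A gene is reliably expressed if its mean TPM across the term's samples is
#' strictly greater than `threshold` (default 100 TPM).
#'
#' @inheritParams mean_expression
#' @param threshold TPM cutoff; strict inequality.
#' @return character vector of expressed gene ids.
#' @export
expressed_genes <- function(matrix, grouping, term_id, threshold = 100) {
  if (threshold < 0) stop("expressed_genes: threshold must be non-negative", call. = FALSE)
  means <- mean_expression(matrix, grouping, term_id)
  names(means)[means > threshold]
}

#' Restrict a global ranking to a context's expressed genes
#'
#' Retained genes keep their global studentized residuals and are re-ranked
#' among themselves; `percentile = 100 * rank / N'` with N' the retained
#' count. Scored genes absent from `expressed` are treated as not expressed
#' and removed (their count is reported via a message).
#'
#' @param global_scores an `intol_scores` data.frame.
#' @param expressed character vector of expressed gene ids.
#' @param term_id optional term label carried through for reporting.
#' @param tpm_threshold optional threshold carried through for reporting.
#' @return object of class `context_ranking`: list with `term_id`,
#'   `expressed`, `scores` (re-ranked data.frame), `tpm_threshold`.
#' @export
context_percentiles <- function(global_scores, expressed, term_id = NA_character_,
                                tpm_threshold = NA_real_) {
  keep <- global_scores$unit_id %in% expressed
  if (!any(keep))
    stop("context_percentiles: no scored gene is expressed in this context", call. = FALSE)
  n_removed <- sum(!keep)
  if (n_removed > 0L)
    message(sprintf("context_percentiles: removed %d scored gene(s) not expressed in context", n_removed))
  direction <- if (identical(attr(global_scores, "orientation"), "damaging_on_total"))
    "descending" else "ascending"
  sc <- global_scores[keep, , drop = FALSE]
  stu <- stats::setNames(sc$studentized, sc$unit_id)
  pct <- to_percentiles(stu, direction = direction)
  sc <- sc[match(pct$unit_id, sc$unit_id), , drop = FALSE]
  sc$rank <- pct$rank
  sc$percentile <- pct$percentile
  rownames(sc) <- NULL
  structure(list(term_id = term_id, expressed = expressed, scores = sc,
                 tpm_threshold = tpm_threshold),
            class = "context_ranking")
}

#' @export
print.context_ranking <- function(x, ...) {
  cat(sprintf("Context ranking for term '%s': %d scored genes retained (TPM threshold %s)\n",
              x$term_id, nrow(x$scores), format(x$tpm_threshold)))
  invisible(x)
}

#' Fold enrichment of disease-gene capture under context re-ranking
#'
#' Ratio between the number of disease genes among the most intolerant
#' (context percentile strictly below `cutoff`) under the context ranking and
#' the number captured by the global ranking at the same cutoff. A
#' fraction-based secondary value (`fold_fraction`, the ratio of the two
#' precisions among top-ranked genes) is returned alongside.
#'
#' @param global_scores an `intol_scores` data.frame.
#' @param context a `context_ranking`.
#' @param disease character vector of disease gene ids (non-empty).
#' @param cutoff percentile cutoff, strict `<` (default 25).
#' @return list: `fold` (NA when the global count is 0), `n_context`,
#'   `n_global`, `fold_fraction`.
#' @export
fold_enrichment <- function(global_scores, context, disease, cutoff = 25) {
  if (length(disease) == 0L) stop("fold_enrichment: disease set is empty", call. = FALSE)
  stopifnot(inherits(context, "context_ranking"))
  top_ctx <- context$scores$unit_id[context$scores$percentile < cutoff]
  top_glob <- global_scores$unit_id[global_scores$percentile < cutoff]
  n_ctx <- length(intersect(disease, top_ctx))
  n_glob <- length(intersect(disease, top_glob))
  frac_ctx <- if (length(top_ctx) > 0L) n_ctx / length(top_ctx) else NA_real_
  frac_glob <- if (length(top_glob) > 0L) n_glob / length(top_glob) else NA_real_
  list(fold = if (n_glob > 0L) n_ctx / n_glob else NA_real_,
       n_context = n_ctx, n_global = n_glob,
       fold_fraction = if (!is.na(frac_glob) && frac_glob > 0) frac_ctx / frac_glob else NA_real_)
}

#' Sweep the TPM expression threshold
#'
#' Applies the expressed-gene filter, context re-ranking, and
#' [fold_enrichment()] at each threshold. Thresholds at which no scored gene
#' survives yield `NA` fold with zero counts.
#'
#' @inheritParams mean_expression
#' @param global_scores an `intol_scores` data.frame.
#' @param disease disease gene set.
#' @param thresholds numeric vector of TPM thresholds (non-empty).
#' @param cutoff percentile cutoff passed to [fold_enrichment()].
#' @return data.frame with columns `threshold`, `fold`, `n_context`,
#'   `n_global`, `n_expressed`.
#' @export
threshold_sweep <- function(matrix, grouping, term_id, global_scores, disease,
                            thresholds, cutoff = 25) {
  if (length(thresholds) == 0L) stop("threshold_sweep: empty threshold list", call. = FALSE)
  if (anyDuplicated(thresholds))
    warning("threshold_sweep: duplicate thresholds produce duplicate rows")
  rows <- lapply(thresholds, function(t) {
    expr <- expressed_genes(matrix, grouping, term_id, threshold = t)
    res <- tryCatch({
      ctx <- suppressMessages(context_percentiles(global_scores, expr, term_id = term_id,
                                                  tpm_threshold = t))
      fe <- fold_enrichment(global_scores, ctx, disease, cutoff = cutoff)
      data.frame(threshold = t, fold = fe$fold, n_context = fe$n_context,
                 n_global = fe$n_global, n_expressed = nrow(ctx$scores))
    }, error = function(e) data.frame(threshold = t, fold = NA_real_, n_context = 0L,
                                      n_global = 0L, n_expressed = 0L))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
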