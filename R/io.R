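# All tabular inputs are tab-separated with a mandatory header row; lines
# starting with '#' are comments. Protein coordinates are 1-based inclusive.

VALID_LABELS  <- c("DAMAGING", "TOLERATED")
VALID_SOURCES <- c("SUPERFAMILY", "PfamA", "PfamB")

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

as_num <- function(x, col, what, allow_na = TRUE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0L)
    stop(sprintf("%s: column '%s' has non-numeric value '%s' at data row %d",
                 what, col, x[bad[1L]], bad[1L]), call. = FALSE)
  if (!allow_na && anyNA(out[x != ""]))
    stop(sprintf("%s: column '%s' has missing values", what, col), call. = FALSE)
  out
}

#' Read a per-variant pathogenicity prediction table
#'
#' Expects a tab-separated file with header columns `gene_id` and `label`
#' (required) and optionally `variant_id`, `protein_id`, `protein_pos`,
#' `score`, and `domain_id` (an explicit domain assignment, which takes
#' precedence over positional interval lookup). Labels are normalized
#' case-insensitively to `DAMAGING`/`TOLERATED`.
#'
#' @param path path to a predictions TSV.
#' @return data.frame with columns `variant_id`, `gene_id`, `protein_id`,
#'   `protein_pos`, `label`, `score` (and `domain_id` when present).
#' @export
read_predictions <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "label"), "predictions")
  if (nrow(df) == 0L) {
    warning("predictions: file contains a header but no data rows")
  }
  label <- toupper(trimws(df$label))
  bad <- which(!(label %in% VALID_LABELS))
  if (length(bad) > 0L)
    stop(sprintf("predictions: unrecognized label '%s' at data row %d (expected DAMAGING or TOLERATED)",
                 df$label[bad[1L]], bad[1L]), call. = FALSE)
  no_gene <- which(is.na(df$gene_id) | trimws(df$gene_id) == "")
  if (length(no_gene) > 0L)
    stop(sprintf("predictions: missing gene_id at data row %d", no_gene[1L]), call. = FALSE)
  nr <- nrow(df)
  out <- data.frame(
    variant_id  = if ("variant_id" %in% names(df)) df$variant_id else sprintf("v%d", seq_len(nr)),
    gene_id     = trimws(df$gene_id),
    protein_id  = if ("protein_id" %in% names(df)) df$protein_id else rep(NA_character_, nr),
    protein_pos = if ("protein_pos" %in% names(df)) as_num(df$protein_pos, "protein_pos", "predictions") else rep(NA_real_, nr),
    label       = label,
    score       = if ("score" %in% names(df)) as_num(df$score, "score", "predictions") else rep(NA_real_, nr),
    stringsAsFactors = FALSE
  )
  if ("domain_id" %in% names(df)) out$domain_id <- df$domain_id
  bad_pos <- which(!is.na(out$protein_pos) & (out$protein_pos < 1 | out$protein_pos != floor(out$protein_pos)))
  if (length(bad_pos) > 0L)
    stop(sprintf("predictions: protein_pos must be a positive integer; got %s at data row %d",
                 out$protein_pos[bad_pos[1L]], bad_pos[1L]), call. = FALSE)
  out
}

#' Read a protein-domain interval table
#'
#' Columns: `protein_id`, `domain_id`, `source` (SUPERFAMILY/PfamA/PfamB),
#' `start`, `end` (1-based inclusive residues). Intervals for one protein may
#' overlap (multi-source annotations).
#'
#' @param path path to a domains TSV.
#' @return data.frame of validated intervals.
#' @export
read_domains <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "domain_id", "source", "start", "end"), "domains")
  start <- as_num(df$start, "start", "domains")
  end   <- as_num(df$end, "end", "domains")
  bad <- which(is.na(start) | is.na(end) | start < 1 | start > end)
  if (length(bad) > 0L)
    stop(sprintf("domains: invalid interval [%s, %s] at data row %d (need 1 <= start <= end)",
                 df$start[bad[1L]], df$end[bad[1L]], bad[1L]), call. = FALSE)
  bad_src <- which(!(df$source %in% VALID_SOURCES))
  if (length(bad_src) > 0L)
    stop(sprintf("domains: unrecognized source '%s' at data row %d (expected %s)",
                 df$source[bad_src[1L]], bad_src[1L], paste(VALID_SOURCES, collapse = "/")),
         call. = FALSE)
  data.frame(protein_id = df$protein_id, domain_id = df$domain_id,
             source = df$source, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Read a genes x samples expression matrix (TPM)
#'
#' First column is the gene id; every remaining header names a sample. Values
#' must be non-negative; duplicate gene or sample ids are rejected.
#'
#' @param path path to an expression TSV.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression: need a gene_id column plus at least one sample column", call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop(sprintf("expression: duplicate gene id '%s'", genes[duplicated(genes)][1L]), call. = FALSE)
  samples <- names(df)[-1L]
  if (anyDuplicated(samples)) stop(sprintf("expression: duplicate sample id '%s'", samples[duplicated(samples)][1L]), call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("expression: non-numeric or missing value in matrix body", call. = FALSE)
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("expression: negative TPM %g for gene '%s', sample '%s'",
                 mat[idx[1L], idx[2L]], genes[idx[1L]], samples[idx[2L]]), call. = FALSE)
  }
  rownames(mat) <- genes
  mat
}

#' Read a context (term to sample) grouping table
#'
#' Columns: `term_id`, `sample_id`; one row per (term, sample) membership.
#' Whether the referenced samples exist in an expression matrix is checked at
#' use time by [mean_expression()].
#'
#' @param path path to a grouping TSV.
#' @return data.frame with columns `term_id`, `sample_id`.
#' @export
read_grouping <- function(path) {
  df <- read_tsv_checked(path, c("term_id", "sample_id"), "grouping")
  unique(data.frame(term_id = df$term_id, sample_id = df$sample_id,
                    stringsAsFactors = FALSE))
}

#' Read a gene set (one gene id per line)
#'
#' `#` comments and blank lines are allowed; members are de-duplicated.
#'
#' @param path path to a gene list file.
#' @param name optional set name (defaults to the file basename).
#' @return character vector of gene ids with a `name` attribute.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("gene set: file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  members <- unique(lines[lines != ""])
  if (length(members) == 0L) stop(sprintf("gene set: no gene ids found in %s", path), call. = FALSE)
  attr(members, "name") <- if (is.null(name)) basename(path) else name
  members
}

#' Read a weighted undirected edge list
#'
#' Columns: `node1`, `node2`, `combined_score`, `experimental_score`.
#' Self-loops are dropped (with a message); duplicate undirected edges —
#' including reversed pairs — are collapsed keeping the maximum of each score.
#'
#' @param path path to an edges TSV.
#' @return data.frame with one row per undirected edge.
#' @export
read_edges <- function(path) {
  df <- read_tsv_checked(path, c("node1", "node2", "combined_score", "experimental_score"), "edges")
  combined <- as_num(df$combined_score, "combined_score", "edges")
  experimental <- as_num(df$experimental_score, "experimental_score", "edges")
  n1 <- df$node1; n2 <- df$node2
  loops <- n1 == n2
  if (any(loops)) {
    message(sprintf("edges: dropped %d self-loop(s)", sum(loops)))
    n1 <- n1[!loops]; n2 <- n2[!loops]
    combined <- combined[!loops]; experimental <- experimental[!loops]
  }
  # canonical orientation so (a,b) and (b,a) collapse
  a <- pmin(n1, n2); b <- pmax(n1, n2)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    message(sprintf("edges: collapsed %d duplicate undirected edge(s), keeping max scores",
                    sum(duplicated(key))))
    combined <- tapply(combined, key, max)
    experimental <- tapply(experimental, key, max)[names(combined)]
    ab <- strsplit(names(combined), "\r", fixed = TRUE)
    a <- vapply(ab, `[`, "", 1L); b <- vapply(ab, `[`, "", 2L)
  }
  out <- data.frame(node1 = unname(a), node2 = unname(b),
                    combined_score = unname(as.numeric(combined)),
                    experimental_score = unname(as.numeric(experimental)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an intolerance score table
#'
#' Writes `unit_id`, `n_total`, `n_damaging`, `residual`, `studentized`,
#' `rank`, `percentile` in ascending percentile order. Numeric fields are
#' written with 12 significant digits so a write/read round trip is lossless
#' at that precision.
#'
#' @param path output path.
#' @param scores a score data.frame as returned by [score_units()].
#' @export
write_scores <- function(path, scores) {
  cols <- c("unit_id", "n_total", "n_damaging", "residual", "studentized", "rank", "percentile")
  miss <- setdiff(cols, names(scores))
  if (length(miss) > 0L)
    stop(sprintf("write_scores: scores lack column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  scores <- scores[order(scores$percentile, scores$unit_id), cols, drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
  body <- data.frame(unit_id = scores$unit_id,
                     n_total = scores$n_total, n_damaging = scores$n_damaging,
                     residual = fmt(scores$residual), studentized = fmt(scores$studentized),
                     rank = fmt(scores$rank), percentile = fmt(scores$percentile),
                     stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path path to a scores TSV.
#' @return data.frame of class `intol_scores`.
#' @export
read_scores <- function(path) {
  df <- read_tsv_checked(path,
                         c("unit_id", "n_total", "n_damaging", "residual",
                           "studentized", "rank", "percentile"), "scores")
  for (col in c("n_total", "n_damaging", "residual", "studentized", "rank", "percentile"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  class(df) <- c("intol_scores", "data.frame")
  df
}
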