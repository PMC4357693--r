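# Seeded generators for every input format, with planted ground truth. A
# single integer seed drives everything; each generator re-seeds with a
# fixed offset from it so adding a generator never perturbs existing
# fixtures. The global RNG state is restored on exit.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a variant prediction table with planted intolerant genes
#'
#' Every gene receives a uniform variant count in
#' `variants_per_gene_range`; labels are drawn independently `DAMAGING` with
#' probability `baseline_p`, except for `planted$count` randomly chosen genes
#' which use `planted$p`. Each gene is given a protein with 1-3
#' non-overlapping domain intervals and variant positions uniform over the
#' protein. Deterministic per seed.
#'
#' @param n_genes number of genes (default 1000).
#' @param variants_per_gene_range integer range, default `c(30, 300)`.
#' @param baseline_p damaging probability for background genes (default 0.15).
#' @param planted list with `count` and `p` (default 50 genes at 0.6).
#' @param seed integer seed.
#' @return list with `predictions` (data.frame), `domains` (data.frame), and
#'   `truth` (list: `intolerant_genes`, `damaging_p`, `protein_len`, `seed`).
#' @export
simulate_variants <- function(n_genes = 1000,
                              variants_per_gene_range = c(30, 300),
                              baseline_p = 0.15,
                              planted = list(count = 50, p = 0.6),
                              seed = 1) {
  if (!(baseline_p > 0 && baseline_p < planted$p && planted$p < 1))
    stop("simulate_variants: need 0 < baseline_p < planted$p < 1", call. = FALSE)
  if (planted$count >= n_genes)
    stop("simulate_variants: planted count must be below n_genes", call. = FALSE)
  with_seed(seed + 101L, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    proteins <- sprintf("P%04d", seq_len(n_genes))
    planted_genes <- sort(sample(genes, planted$count))
    p_gene <- stats::setNames(rep(baseline_p, n_genes), genes)
    p_gene[planted_genes] <- planted$p
    protein_len <- stats::setNames(sample(400:2400, n_genes, replace = TRUE), proteins)

    dom_rows <- lapply(seq_len(n_genes), function(i) {
      len <- protein_len[i]
      k <- sample(1:3, 1)
      # place k non-overlapping intervals left to right with random gaps
      widths <- sample(80:280, k, replace = TRUE)
      gaps <- sample(10:120, k, replace = TRUE)
      starts <- cumsum(gaps + c(0, widths[-k]))
      ends <- pmin(starts + widths - 1L, len)
      ok <- starts <= len & starts <= ends
      if (!any(ok)) { starts <- 1L; ends <- min(100L, len); ok <- TRUE; k <- 1L }
      data.frame(protein_id = proteins[i],
                 domain_id = sprintf("D%04d_%d", i, seq_len(k))[ok],
                 source = sample(VALID_SOURCES, sum(ok), replace = TRUE),
                 start = as.integer(starts[ok]), end = as.integer(ends[ok]),
                 stringsAsFactors = FALSE)
    })
    domains <- do.call(rbind, dom_rows)

    n_var <- sample(variants_per_gene_range[1]:variants_per_gene_range[2],
                    n_genes, replace = TRUE)
    gene_idx <- rep(seq_len(n_genes), n_var)
    total <- length(gene_idx)
    pos <- vapply(gene_idx, function(i) sample.int(protein_len[i], 1L), integer(1))
    lab <- ifelse(stats::runif(total) < p_gene[gene_idx], "DAMAGING", "TOLERATED")
    predictions <- data.frame(
      variant_id = sprintf("var%06d", seq_len(total)),
      gene_id = genes[gene_idx],
      protein_id = proteins[gene_idx],
      protein_pos = pos,
      label = lab,
      score = round(stats::rnorm(total, ifelse(lab == "DAMAGING", -3, 2), 1), 3),
      stringsAsFactors = FALSE)
    list(predictions = predictions, domains = domains,
         truth = list(intolerant_genes = planted_genes, damaging_p = p_gene,
                      protein_len = protein_len, seed = seed))
  })
}

#' Simulate a TPM expression matrix with planted tissue restriction
#'
#' Restricted genes exceed the reliable-expression threshold (100 TPM) only
#' in their home term; ubiquitous genes exceed it in every term. Per-gene
#' base levels are drawn away from the threshold (high around `high_tpm`
#' with a multiplicative factor in [0.5, 1.5], low at `low_tpm`) and
#' per-sample values jitter the base by at most 10%, so the planted
#' expressed sets are recovered exactly at the 100 TPM cutoff.
#'
#' @param genes character vector of gene ids.
#' @param terms character vector of context term ids.
#' @param restricted_fraction fraction of genes that are tissue-restricted
#'   (ignored when `restricted_genes` is given).
#' @param high_tpm expressed base level (default 300 TPM).
#' @param low_tpm non-expressed base level (default 5 TPM).
#' @param seed integer seed.
#' @param samples_per_term samples per context term (default 3).
#' @param restricted_genes optional explicit set of restricted genes.
#' @param home_terms optional named vector gene -> home term for restricted
#'   genes.
#' @return list with `expression` (matrix), `grouping` (data.frame), and
#'   `truth` (list: `restricted` named gene -> home term, `expressed_sets`
#'   per term, `seed`).
#' @export
simulate_expression <- function(genes, terms, restricted_fraction = 0.3,
                                high_tpm = 300, low_tpm = 5, seed = 1,
                                samples_per_term = 3,
                                restricted_genes = NULL, home_terms = NULL) {
  if (low_tpm >= 100 || high_tpm * 0.5 <= 100)
    stop("simulate_expression: need low_tpm < 100 and high_tpm/2 > 100 so planted sets are unambiguous",
         call. = FALSE)
  with_seed(seed + 202L, {
    if (is.null(restricted_genes))
      restricted_genes <- sort(sample(genes, round(restricted_fraction * length(genes))))
    if (is.null(home_terms))
      home_terms <- stats::setNames(sample(terms, length(restricted_genes), replace = TRUE),
                                    restricted_genes)
    samples <- as.vector(vapply(terms, function(t) paste0(t, "_s", seq_len(samples_per_term)),
                                character(samples_per_term)))
    grouping <- data.frame(term_id = rep(terms, each = samples_per_term),
                           sample_id = samples, stringsAsFactors = FALSE)
    base <- matrix(0, nrow = length(genes), ncol = length(terms),
                   dimnames = list(genes, terms))
    hi <- function(n) high_tpm * stats::runif(n, 0.5, 1.5)
    base[, ] <- low_tpm
    ubi <- setdiff(genes, restricted_genes)
    base[ubi, ] <- hi(length(ubi) * length(terms))
    for (g in restricted_genes) base[g, home_terms[g]] <- hi(1L)
    expr <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      t <- grouping$term_id[j]
      expr[, j] <- base[, t] * stats::runif(length(genes), 0.9, 1.1)
    }
    expressed_sets <- lapply(stats::setNames(terms, terms), function(t)
      sort(c(ubi, names(home_terms)[home_terms == t])))
    list(expression = expr, grouping = grouping,
         truth = list(restricted = home_terms, expressed_sets = expressed_sets,
                      seed = seed))
  })
}

#' Simulate a scored interactome with a planted intolerant subnetwork
#'
#' An Erdos-Renyi background graph plus one planted clique whose members'
#' studentized residuals are shifted by `residual_shift` standard deviations.
#' Edge scores are drawn so that the documented high-confidence filter
#' (combined > 500 and experimental > 0) retains exactly the intended graph;
#' a batch of decoy edges failing the filter is added to exercise it.
#'
#' @param n_nodes number of genes (default 300).
#' @param background_edge_p background edge probability (default 0.02).
#' @param clique_size planted clique size (default 15).
#' @param attach_p probability that a planted member links to any given
#'   background node (default 0.02).
#' @param residual_shift shift applied to planted members' residuals
#'   (default -2).
#' @param seed integer seed.
#' @return list with `edges` (data.frame incl. decoys), `scores`
#'   (data.frame `unit_id`, `studentized`, `rank`, `percentile`), and
#'   `truth` (list: `planted`, `kept_edges`, `seed`).
#' @export
simulate_network <- function(n_nodes = 300, background_edge_p = 0.02,
                             clique_size = 15, attach_p = 0.02,
                             residual_shift = -2, seed = 1) {
  if (clique_size >= n_nodes)
    stop("simulate_network: clique_size must be below n_nodes", call. = FALSE)
  with_seed(seed + 303L, {
    nodes <- sprintf("N%04d", seq_len(n_nodes))
    planted <- sort(sample(nodes, clique_size))
    pairs <- t(utils::combn(nodes, 2L))
    in_clique <- pairs[, 1] %in% planted & pairs[, 2] %in% planted
    one_planted <- xor(pairs[, 1] %in% planted, pairs[, 2] %in% planted)
    u <- stats::runif(nrow(pairs))
    keep <- in_clique | (one_planted & u < attach_p) |
      (!in_clique & !one_planted & u < background_edge_p)
    kept <- pairs[keep, , drop = FALSE]
    nk <- nrow(kept)
    edges <- data.frame(node1 = kept[, 1], node2 = kept[, 2],
                        combined_score = round(stats::runif(nk, 550, 999)),
                        experimental_score = round(stats::runif(nk, 10, 900)),
                        stringsAsFactors = FALSE)
    # decoys that the filter must drop: low combined, or zero experimental
    decoy_idx <- which(!keep)
    decoy_idx <- decoy_idx[sample.int(length(decoy_idx), min(100L, length(decoy_idx)))]
    half <- length(decoy_idx) %/% 2L
    decoys <- data.frame(node1 = pairs[decoy_idx, 1], node2 = pairs[decoy_idx, 2],
                         combined_score = c(round(stats::runif(half, 100, 500)),
                                            round(stats::runif(length(decoy_idx) - half, 550, 999))),
                         experimental_score = c(round(stats::runif(half, 10, 900)),
                                                rep(0, length(decoy_idx) - half)),
                         stringsAsFactors = FALSE)
    stu <- stats::rnorm(n_nodes)
    names(stu) <- nodes
    stu[planted] <- stu[planted] + residual_shift
    scores <- to_percentiles(stu)
    class(scores) <- c("intol_scores", "data.frame")
    list(edges = rbind(edges, decoys), scores = scores,
         truth = list(planted = planted, kept_edges = edges, seed = seed))
  })
}

#' Write a simulated fixture set to a directory
#'
#' Emits the exact TSV dialects consumed by the readers: `predictions.tsv`,
#' `domains.tsv`, `expression.tsv`, `grouping.tsv`, `edges.tsv`, and
#' `truth_*.txt` gene lists.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed driving all generators.
#' @param n_genes,n_nodes sizes passed through to the generators.
#' @return invisibly, the list of files written.
#' @export
write_simulation <- function(dir, seed = 1, n_genes = 1000, n_nodes = 300) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_variants(n_genes = n_genes,
                           planted = list(count = max(2L, round(0.05 * n_genes)), p = 0.6),
                           seed = seed)
  terms <- c("UBERON:0001017", "UBERON:0001009", "UBERON:0002405")
  ex <- simulate_expression(sort(unique(sim$predictions$gene_id)), terms, seed = seed)
  net <- simulate_network(n_nodes = n_nodes, seed = seed)
  files <- c(predictions = file.path(dir, "predictions.tsv"),
             domains = file.path(dir, "domains.tsv"),
             expression = file.path(dir, "expression.tsv"),
             grouping = file.path(dir, "grouping.tsv"),
             edges = file.path(dir, "edges.tsv"),
             network_scores = file.path(dir, "network_scores.tsv"),
             truth = file.path(dir, "truth_intolerant_genes.txt"))
  utils::write.table(sim$predictions, files["predictions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$domains, files["domains"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr_df <- data.frame(gene_id = rownames(ex$expression), ex$expression,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr_df, files["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ex$grouping, files["grouping"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, files["edges"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nsc <- net$scores
  nsc$n_total <- NA_integer_; nsc$n_damaging <- NA_integer_
  nsc$residual <- nsc$studentized
  write_scores(files["network_scores"], nsc)
  writeLines(c("# planted intolerant genes", sim$truth$intolerant_genes), files["truth"])
  invisible(files)
}

#' Simulate a complete tissue-context study
#'
#' Builds the coupled fixture used to exercise context re-ranking end to
#' end: a variant table with two planted tiers — strongly intolerant
#' competitor genes restricted to a non-target tissue, and moderately
#' intolerant disease genes restricted to the target tissue with home-tissue
#' base TPM uniform in [120, 450] — plus ubiquitously expressed background.
#' Over-stringent TPM filtering therefore drops the true disease genes,
#' making the threshold sweep unimodal by construction.
#'
#' @param seed integer seed.
#' @param n_genes total genes (default 1000).
#' @param n_competitors strongly intolerant non-disease genes (default 150).
#' @param n_disease moderately intolerant disease genes (default 30).
#' @param p_strong,p_moderate,p_baseline damaging probabilities
#'   (defaults 0.5, 0.22, 0.15).
#' @return list: `scores` (global `intol_scores`), `expression`, `grouping`,
#'   `term_id` (the target tissue), `disease` (gene set), and `truth`.
#' @export
simulate_tissue_study <- function(seed = 1, n_genes = 1000,
                                  n_competitors = 150, n_disease = 30,
                                  p_strong = 0.5, p_moderate = 0.22,
                                  p_baseline = 0.15) {
  sim <- simulate_variants(n_genes = n_genes, baseline_p = p_baseline,
                           planted = list(count = n_competitors, p = p_strong),
                           seed = seed)
  genes <- sort(unique(sim$predictions$gene_id))
  competitors <- sim$truth$intolerant_genes
  with_seed(seed + 404L, {
    disease <- sort(sample(setdiff(genes, competitors), n_disease))
    # re-label the disease genes' variants at the moderate damaging rate
    idx <- sim$predictions$gene_id %in% disease
    sim$predictions$label[idx] <-
      ifelse(stats::runif(sum(idx)) < p_moderate, "DAMAGING", "TOLERATED")
    target <- "UBERON:0001017"
    other <- "UBERON:9999999"
    # half the background is ubiquitous; competitors live only in the other
    # tissue; disease genes only in the target tissue, at 120-450 TPM
    background <- setdiff(genes, c(competitors, disease))
    restricted_bg <- sample(background, round(0.5 * length(background)))
    restricted <- c(competitors, disease, restricted_bg)
    home <- stats::setNames(c(rep(other, length(competitors)),
                              rep(target, length(disease)),
                              sample(c(target, other), length(restricted_bg), replace = TRUE)),
                            restricted)
    # ubiquitous base 300-900 TPM so a 500-TPM filter still retains a ranking
    ex <- simulate_expression(genes, c(target, other), seed = seed,
                              high_tpm = 600,
                              restricted_genes = restricted, home_terms = home)
    # overwrite disease genes' home-tissue level: uniform 120-450 TPM so a
    # 500-TPM filter removes them while 100-200 TPM keeps them
    target_samples <- ex$grouping$sample_id[ex$grouping$term_id == target]
    for (g in disease) {
      b <- stats::runif(1, 120, 450)
      ex$expression[g, target_samples] <- b * stats::runif(length(target_samples), 0.95, 1.05)
    }
    scores <- score_units(sim$predictions, by = "gene")
    list(scores = scores, expression = ex$expression, grouping = ex$grouping,
         term_id = target, disease = disease,
         truth = list(competitors = competitors, disease = disease, seed = seed))
  })
}
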