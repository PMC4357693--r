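# Interactome intolerance analysis: filter a weighted edge list to
# high-confidence experimentally supported edges, cluster the resulting
# graph with the MCODE (molecular complex detection) algorithm, and test
# each cluster's intolerance-score distribution against the background with
# a Mann-Whitney U test under Bonferroni control.

#' Filter a weighted edge list into a high-confidence graph
#'
#' Keeps edges with `combined_score > min_combined` AND
#' `experimental_score > min_experimental` (both strict); nodes left without
#' edges are dropped.
#'
#' @param edges data.frame from [read_edges()].
#' @param min_combined combined-score threshold (default 500, strict).
#' @param min_experimental experimental-score threshold (default 0, strict).
#' @return an undirected simple [igraph::graph] on the surviving nodes.
#' @export
filter_edges <- function(edges, min_combined = 500, min_experimental = 0) {
  keep <- edges$combined_score > min_combined & edges$experimental_score > min_experimental
  kept <- edges[keep, c("node1", "node2"), drop = FALSE]
  if (nrow(kept) == 0L)
    warning("filter_edges: no edge passes the filter; returning an empty graph")
  g <- igraph::graph_from_data_frame(kept, directed = FALSE)
  igraph::simplify(g)
}

neighborhood_core <- function(graph, v) {
  nb <- igraph::neighbors(graph, v)
  if (length(nb) < 2L) return(list(k = 0L, density = 0))
  gn <- igraph::induced_subgraph(graph, nb)
  if (igraph::ecount(gn) == 0L) return(list(k = 0L, density = 0))
  core <- igraph::coreness(gn)
  k <- max(core)
  sub <- igraph::induced_subgraph(gn, which(core == k))
  nv <- igraph::vcount(sub)
  dens <- if (nv < 2L) 0 else 2 * igraph::ecount(sub) / (nv * (nv - 1))
  list(k = k, density = dens)
}

#' MCODE vertex weights
#'
#' For each vertex v the induced subgraph on its open neighborhood is built,
#' its highest k-core extracted, and `weight(v) = k * density` of that core
#' (density = 2E / V(V-1)). Vertices with degree below `degree_cutoff`
#' receive weight 0, as do vertices whose neighborhood contains no edge.
#'
#' @param graph an undirected simple igraph graph.
#' @param degree_cutoff minimum degree for a non-zero weight (default 2).
#' @return named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(graph, degree_cutoff = 2) {
  nm <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  w <- numeric(length(nm)); names(w) <- nm
  for (i in seq_along(nm)) {
    if (deg[i] < degree_cutoff) next
    nc <- neighborhood_core(graph, nm[i])
    w[i] <- nc$k * nc$density
  }
  w
}

#' MCODE molecular-complex detection
#'
#' Seeds at the highest-weight vertex not yet assigned to a cluster (weight
#' ties broken by lexicographic vertex id; only positive-weight vertices
#' seed) and grows the cluster breadth-first, admitting neighbors whose
#' weight is at least `seed_weight * (1 - vwp)` and that belong to no other
#' cluster, to at most `max_depth` hops. The optional haircut takes the
#' 2-core of the candidate cluster, removing singly connected members.
#' Clusters of fewer than 2 members are discarded; output is sorted by
#' `score = density * size` descending.
#'
#' @param graph an undirected simple igraph graph.
#' @param vwp vertex weight percentage (default 0.2).
#' @param haircut remove singly connected members (default TRUE).
#' @param fluff unsupported expansion step, must be FALSE (the published
#'   default).
#' @param degree_cutoff minimum degree for seeding weights (default 2).
#' @param max_depth breadth-first expansion depth limit (default 100).
#' @return list of clusters, each a list with `cluster_id`, `members`,
#'   `seed_node`, `mcode_score`, `density`.
#' @export
mcode_clusters <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                           degree_cutoff = 2, max_depth = 100) {
  if (!identical(fluff, FALSE)) stop("mcode_clusters: fluff expansion is not implemented", call. = FALSE)
  if (vwp < 0 || vwp > 1) stop("mcode_clusters: vwp must be in [0, 1]", call. = FALSE)
  w <- mcode_vertex_weights(graph, degree_cutoff = degree_cutoff)
  nm <- names(w)
  order_idx <- order(-w, nm)  # weight desc, id asc for determinism
  assigned <- character(0)
  clusters <- list()
  for (i in order_idx) {
    seed <- nm[i]
    if (w[i] <= 0) next
    if (seed %in% assigned) next
    threshold <- w[i] * (1 - vwp)
    members <- seed
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in igraph::V(graph)$name[igraph::neighbors(graph, v)]) {
          if (u %in% members || u %in% assigned) next
          if (w[u] >= threshold) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- sort(unique(nxt))
      depth <- depth + 1L
    }
    if (haircut && length(members) > 1L) {
      sub <- igraph::induced_subgraph(graph, members)
      core <- igraph::coreness(sub)
      members <- igraph::V(sub)$name[core >= 2]
    }
    if (length(members) < 2L) {
      assigned <- c(assigned, seed)
      next
    }
    sub <- igraph::induced_subgraph(graph, members)
    nv <- igraph::vcount(sub)
    dens <- 2 * igraph::ecount(sub) / (nv * (nv - 1))
    clusters[[length(clusters) + 1L]] <- list(
      members = sort(members), seed_node = seed,
      mcode_score = dens * nv, density = dens)
    assigned <- c(assigned, members, seed)
  }
  if (length(clusters) == 0L) return(list())
  ord <- order(-vapply(clusters, `[[`, numeric(1), "mcode_score"),
               -vapply(clusters, function(cl) length(cl$members), integer(1)),
               vapply(clusters, `[[`, character(1), "seed_node"))
  clusters <- clusters[ord]
  for (j in seq_along(clusters)) clusters[[j]]$cluster_id <- sprintf("C%03d", j)
  clusters
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation enumeration on midranks when both samples have at most
#' `exact_max` observations (so the p-value is exact even with ties);
#' otherwise a normal approximation with tie correction and continuity
#' correction. Returns the U statistic for the first sample.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-sample size for the exact branch (default 8).
#' @return list with `U`, `p_value`, `method`.
#' @export
mwu_test <- function(x, y, exact_max = 8) {
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stop("mwu_test: both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled, ties.method = "average")
  U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n <= exact_max && m <= exact_max) {
    idx <- utils::combn(n + m, n)
    stat <- colSums(matrix(rk[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(stat - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- n + m
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n * m / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "approx"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "approx")
}

#' Test each cluster's intolerance against the background
#'
#' For every cluster with at least `min_members` scored members, compares the
#' members' studentized residuals with the background (scored members of the
#' other clusters by default, or all other scored genes) by a two-sided
#' Mann-Whitney U test. Direction is `INTOLERANT` when the member median
#' residual is below the background median. Bonferroni control divides
#' `alpha` by the number of clusters actually tested.
#'
#' @param clusters list from [mcode_clusters()].
#' @param scores an `intol_scores` data.frame (or any data.frame with
#'   `unit_id` and `studentized`).
#' @param background `"other_clustered"` (default) or `"all_scored"`.
#' @param min_members minimum scored members for a cluster to be tested
#'   (default 10).
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with one row per tested cluster: `cluster_id`,
#'   `n_members_scored`, `U`, `p_value`, `direction`,
#'   `significant_bonferroni`, `alpha_adjusted`.
#' @export
cluster_intolerance_tests <- function(clusters, scores,
                                      background = c("other_clustered", "all_scored"),
                                      min_members = 10, alpha = 0.05) {
  background <- match.arg(background)
  stu <- stats::setNames(scores$studentized, scores$unit_id)
  scored_members <- lapply(clusters, function(cl) intersect(cl$members, names(stu)))
  n_scored <- vapply(scored_members, length, integer(1))
  eligible <- which(n_scored >= min_members)
  small <- which(n_scored < 2L)
  if (length(small) > 0L)
    warning(sprintf("cluster_intolerance_tests: %d cluster(s) with fewer than 2 scored members skipped",
                    length(small)))
  if (length(eligible) == 0L)
    stop(sprintf("cluster_intolerance_tests: no cluster has >= %d scored members", min_members),
         call. = FALSE)
  alpha_adj <- alpha / length(eligible)
  all_clustered <- unique(unlist(scored_members))
  rows <- lapply(eligible, function(i) {
    memb <- scored_members[[i]]
    bg_genes <- if (background == "other_clustered")
      setdiff(all_clustered, memb)
    else
      setdiff(names(stu), memb)
    if (length(bg_genes) == 0L)
      stop("cluster_intolerance_tests: empty background; try background = 'all_scored'", call. = FALSE)
    xv <- stu[memb]; yv <- stu[bg_genes]
    tst <- mwu_test(xv, yv)
    data.frame(cluster_id = clusters[[i]]$cluster_id,
               n_members_scored = length(memb),
               U = tst$U, p_value = tst$p_value,
               direction = if (stats::median(xv) < stats::median(yv)) "INTOLERANT" else "TOLERANT",
               significant_bonferroni = tst$p_value < alpha_adj,
               alpha_adjusted = alpha_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
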