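edge_df <- function(n1, n2, comb = 600, exp = 10) {
  data.frame(node1 = n1, node2 = n2, combined_score = comb,
             experimental_score = exp, stringsAsFactors = FALSE)
}

complete_edges <- function(nodes, comb = 600, exp = 10) {
  pr <- t(combn(nodes, 2))
  edge_df(pr[, 1], pr[, 2], comb, exp)
}

test_that("edge filtering is strict on both scores and drops isolated nodes", {
  e <- edge_df(c("A", "A", "A", "B"), c("B", "C", "D", "C"),
               comb = c(501, 500, 900, 700), exp = c(1, 10, 0, 4))
  g <- filter_edges(e)
  expect_equal(igraph::ecount(g), 2L)  # only (A,B,501,1) and (B,C,700,4)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_warning(g0 <- filter_edges(edge_df("A", "B", comb = 100, exp = 0)),
                 "no edge")
  expect_equal(igraph::vcount(g0), 0L)
  # idempotence: refiltering the surviving graph changes nothing
  surv <- igraph::as_data_frame(g)
  e2 <- edge_df(surv$from, surv$to,
                comb = e$combined_score[match(paste(surv$from, surv$to),
                                              paste(e$node1, e$node2))],
                exp = e$experimental_score[match(paste(surv$from, surv$to),
                                                 paste(e$node1, e$node2))])
  g2 <- filter_edges(e2)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})

test_that("MCODE vertex weights follow the k-core-times-density definition", {
  # any vertex of K5: neighborhood K4, highest core k = 3, density 1 -> weight 3
  g <- filter_edges(complete_edges(LETTERS[1:5]))
  w <- mcode_vertex_weights(g)
  expect_equal(unname(w), rep(3, 5))
  # star centre: leaves mutually non-adjacent -> weight 0
  star <- filter_edges(edge_df(rep("hub", 4), paste0("leaf", 1:4)))
  expect_equal(unname(mcode_vertex_weights(star)), rep(0, 5))
  # weights invariant under relabeling
  relab <- filter_edges(complete_edges(c("z9", "q1", "m5", "a2", "x7")))
  expect_equal(sort(unname(mcode_vertex_weights(relab))), sort(unname(w)))
})

test_that("MCODE recovers a planted clique and haircut trims pendants", {
  # disjoint union of K6 and a 20-node path: the single cluster is the K6
  k6 <- complete_edges(paste0("k", 1:6))
  path <- edge_df(paste0("p", 1:19), paste0("p", 2:20))
  g <- filter_edges(rbind(k6, path))
  cl <- mcode_clusters(g)
  expect_equal(length(cl), 1L)
  expect_setequal(cl[[1]]$members, paste0("k", 1:6))
  expect_equal(cl[[1]]$mcode_score, 6)  # density 1 x size 6

  # K4 plus a pendant: with the weight threshold open (vwp = 1) the pendant
  # joins the candidate cluster and only the haircut removes it
  k4p <- rbind(complete_edges(paste0("c", 1:4)), edge_df("c1", "pend"))
  gp <- filter_edges(k4p)
  with_hair <- mcode_clusters(gp, vwp = 1, haircut = TRUE)
  expect_setequal(with_hair[[1]]$members, paste0("c", 1:4))
  without <- mcode_clusters(gp, vwp = 1, haircut = FALSE)
  expect_true("pend" %in% without[[1]]$members)

  # isomorphic relabeled graph yields isomorphic clusters
  relab <- rbind(complete_edges(paste0("K", 1:6)), edge_df(paste0("P", 1:19), paste0("P", 2:20)))
  cl2 <- mcode_clusters(filter_edges(relab))
  expect_equal(length(cl2[[1]]$members), length(cl[[1]]$members))
  expect_equal(cl2[[1]]$mcode_score, cl[[1]]$mcode_score)
})

test_that("MCODE clusters are disjoint connected subgraphs on random graphs", {
  set.seed(47)
  for (i in 1:3) {
    g <- igraph::sample_gnp(80, 0.08)
    igraph::V(g)$name <- sprintf("n%02d", 1:80)
    cl <- mcode_clusters(g)
    all_members <- unlist(lapply(cl, `[[`, "members"))
    expect_equal(anyDuplicated(all_members), 0L)
    for (c in cl) {
      sub <- igraph::induced_subgraph(g, c$members)
      expect_true(igraph::is_connected(sub))
      expect_gte(length(c$members), 2L)
    }
  }
})

test_that("the Mann-Whitney test agrees with enumeration and wilcox.test", {
  set.seed(53)
  # same multiset in both samples: exact two-sided p is 1
  expect_equal(mwu_test(c(1, 2, 3, 4), c(4, 3, 2, 1))$p_value, 1)
  # 3 lowest vs 3 highest ranks: two-sided p = 2 / C(6,3)
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6))$p_value, 2 / choose(6, 3),
               tolerance = 1e-12)
  # exact branch vs the pair-count enumeration oracle, ties included
  for (i in 1:10) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(1:5, n, replace = TRUE); y <- sample(1:5, m, replace = TRUE)
    expect_equal(mwu_test(x, y)$p_value, mwu_enum(x, y), tolerance = 1e-12)
  }
  # tie-free exact branch equals wilcox.test's exact p
  x <- c(1.3, 2.7, 0.2, 5.1); y <- c(3.3, 4.8, 6.2, 0.9, 2.1)
  expect_equal(mwu_test(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # approximate and exact p agree within 0.01 at n = m = 9
  for (i in 1:5) {
    x <- rnorm(9); y <- rnorm(9, 0.5)
    exact <- mwu_test(x, y, exact_max = 9)$p_value
    approx <- mwu_test(x, y, exact_max = 8)$p_value
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("cluster tests report direction and Bonferroni-adjusted significance", {
  clusters <- list(
    list(cluster_id = "C001", members = sprintf("a%02d", 1:12), seed_node = "a01", mcode_score = 3),
    list(cluster_id = "C002", members = sprintf("b%02d", 1:12), seed_node = "b01", mcode_score = 2),
    list(cluster_id = "C003", members = c("t1", "t2"), seed_node = "t1", mcode_score = 1))
  set.seed(59)
  stu <- c(setNames(rnorm(12, -3), sprintf("a%02d", 1:12)),
           setNames(rnorm(12, 0), sprintf("b%02d", 1:12)),
           setNames(rnorm(2, 0), c("t1", "t2")))
  scores <- make_scores(unname(stu), ids = names(stu))
  tests <- cluster_intolerance_tests(clusters, scores, min_members = 10)
  expect_equal(nrow(tests), 2L)  # C003 is below min_members
  expect_equal(tests$alpha_adjusted, rep(0.025, 2))
  a_row <- tests[tests$cluster_id == "C001", ]
  expect_equal(a_row$direction, "INTOLERANT")
  expect_true(a_row$significant_bonferroni)
  expect_error(cluster_intolerance_tests(clusters, scores, min_members = 50),
               "no cluster")
})
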