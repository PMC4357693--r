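test_that("counts aggregate per gene and per overlapping domain", {
  v <- data.frame(gene_id = c("G", "G", "G"), label = c("DAMAGING", "TOLERATED", "TOLERATED"),
                  stringsAsFactors = FALSE)
  cnt <- aggregate_counts(v, by = "gene")
  expect_equal(cnt, data.frame(unit_id = "G", n_total = 3L, n_damaging = 1L,
                               stringsAsFactors = FALSE))

  # position 50 of protein P lies in A[10,100] and B[40,60]: counted in both
  v2 <- data.frame(gene_id = "G", protein_id = "P", protein_pos = 50,
                   label = "DAMAGING", stringsAsFactors = FALSE)
  dom <- data.frame(protein_id = "P", domain_id = c("A", "B"),
                    source = "PfamA", start = c(10L, 40L), end = c(100L, 60L),
                    stringsAsFactors = FALSE)
  cnt2 <- aggregate_counts(v2, by = "domain", domains = dom)
  expect_setequal(cnt2$unit_id, c("A", "B"))
  expect_equal(cnt2$n_total, c(1L, 1L))

  # missing position under by = "domain" is excluded with a warning
  v3 <- rbind(v2, data.frame(gene_id = "G", protein_id = "P", protein_pos = NA,
                             label = "TOLERATED"))
  expect_warning(cnt3 <- aggregate_counts(v3, by = "domain", domains = dom),
                 "excluded")
  expect_equal(sum(cnt3$n_total), 2L)

  # explicit domain_id wins over positional lookup
  v4 <- v2; v4$domain_id <- "X"
  cnt4 <- aggregate_counts(v4, by = "domain", domains = dom)
  expect_equal(cnt4$unit_id, "X")

  expect_error(aggregate_counts(v2, by = "domain"), "domain")
})

test_that("the mutation-load regression matches the normal equations and flags degenerate designs", {
  cnt <- data.frame(unit_id = letters[1:6],
                    n_damaging = c(1L, 2L, 5L, 8L, 3L, 9L),
                    n_total = c(10L, 12L, 15L, 18L, 30L, 20L))
  fit <- fit_regression(cnt)
  ora <- normal_equations(cnt$n_damaging, cnt$n_total)
  expect_equal(fit$intercept, unname(ora["intercept"]), tolerance = 1e-12)
  expect_equal(fit$slope, unname(ora["slope"]), tolerance = 1e-12)
  # OLS identities
  expect_lt(abs(sum(fit$residuals)), 1e-9 * sum(abs(fit$residuals)) + 1e-12)
  expect_equal(sum(fit$leverages), 2, tolerance = 1e-10)

  # perfect line -> zero residual variance
  perfect <- data.frame(unit_id = c("a", "b", "c"), n_damaging = 0:2, n_total = 2:4)
  expect_error(fit_regression(perfect), "degenerate")
  # too few units
  expect_error(fit_regression(cnt[1:2, ]), "at least 3")
  # identical predictor values
  same_x <- data.frame(unit_id = c("a", "b", "c"), n_damaging = c(2L, 2L, 2L),
                       n_total = c(5L, 7L, 9L))
  expect_error(fit_regression(same_x), "singular")
  # reversed orientation swaps response and predictor
  fit_r <- fit_regression(cnt, orientation = "damaging_on_total")
  ora_r <- normal_equations(cnt$n_total, cnt$n_damaging)
  expect_equal(fit_r$slope, unname(ora_r["slope"]), tolerance = 1e-12)
})

test_that("studentized residuals equal explicit leave-one-out refits and rstudent", {
  set.seed(11)
  x <- rpois(10, 8); y <- 2 * x + 5 + rnorm(10, sd = 3)
  cnt <- data.frame(unit_id = sprintf("u%02d", 1:10),
                    n_damaging = x, n_total = round(pmax(y, x + 1)))
  fit <- fit_regression(cnt)
  r <- studentize(fit)
  oracle <- loo_studentized(cnt$n_damaging, cnt$n_total)
  expect_equal(unname(r), oracle, tolerance = 1e-10)
  lmfit <- lm(n_total ~ n_damaging, data = cnt)
  expect_equal(unname(r), unname(rstudent(lmfit)), tolerance = 1e-10)

  # mirrored fixture: residuals +d and -d at equal leverage give opposite r
  cnt2 <- data.frame(unit_id = letters[1:6], n_damaging = c(1, 1, 3, 3, 5, 5),
                     n_total = c(8, 12, 13, 17, 18, 22))
  r2 <- studentize(fit_regression(cnt2))
  expect_equal(r2[["a"]], -r2[["b"]], tolerance = 1e-12)
  expect_equal(r2[["e"]], -r2[["f"]], tolerance = 1e-12)

  # internal studentization follows e / (s * sqrt(1 - h))
  ri <- studentize(fit, type = "internal")
  expect_equal(unname(ri),
               unname(fit$residuals / (fit$residual_se * sqrt(1 - fit$leverages))),
               tolerance = 1e-12)
})

test_that("percentiles are 100 * rank / N with average ranks at ties", {
  expect_equal(to_percentiles(c(a = -2, b = -1, c = 0, d = 1))$percentile,
               c(25, 50, 75, 100))
  # unique minimum among 100 distinct values falls in the first percentile
  set.seed(3)
  v <- setNames(sample(seq(-5, 5, length.out = 100)), sprintf("g%03d", 1:100))
  p <- to_percentiles(v)
  expect_equal(p$percentile[which.min(p$studentized)], 1)
  # all tied, N = 4: every rank 2.5, every percentile 62.5
  p4 <- to_percentiles(c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(p4$rank, rep(2.5, 4))
  expect_equal(p4$percentile, rep(62.5, 4))
  # descending direction reverses the ranking
  pd <- to_percentiles(c(a = -2, b = 2), direction = "descending")
  expect_equal(pd$unit_id[pd$percentile == 50], "b")
  expect_error(to_percentiles(c(a = NaN, b = NA)), "no finite")
})

test_that("score_units is invariant to input row order", {
  set.seed(21)
  v <- make_predictions(n_total = sample(10:40, 20, replace = TRUE),
                        n_damaging = sample(1:9, 20, replace = TRUE))
  s1 <- score_units(v, by = "gene")
  s2 <- score_units(v[sample(nrow(v)), ], by = "gene")
  expect_equal(s1, s2)
})

test_that("a small intolerant domain is flagged while its gene stays unremarkable", {
  # one 200-residue domain of a 1166-residue protein carries all the
  # damaging variants; the rest of the protein is benign and mutation-heavy
  set.seed(5)
  bg <- make_predictions(n_total = sample(20:60, 40, replace = TRUE),
                         n_damaging = sample(3:12, 40, replace = TRUE))
  focal_n <- 90L
  pos <- c(sample(400:599, 18, replace = TRUE),      # damaging, inside domain
           sample(c(1:399, 600:1166), focal_n - 18, replace = TRUE))
  focal <- data.frame(variant_id = sprintf("f%02d", 1:focal_n), gene_id = "GFOC",
                      protein_id = "PFOC", protein_pos = pos,
                      label = c(rep("DAMAGING", 18), rep("TOLERATED", focal_n - 18)),
                      score = 0, stringsAsFactors = FALSE)
  v <- rbind(bg, focal)
  gene_scores <- score_units(v, by = "gene")
  expect_gt(gene_scores$percentile[gene_scores$unit_id == "GFOC"], 25)

  doms <- do.call(rbind, lapply(unique(bg$protein_id), function(p)
    data.frame(protein_id = p, domain_id = paste0("D", p), source = "PfamA",
               start = 1L, end = 100L, stringsAsFactors = FALSE)))
  doms <- rbind(doms,
                data.frame(protein_id = "PFOC", domain_id = c("DFOC", "DREST"),
                           source = c("SUPERFAMILY", "PfamB"),
                           start = c(400L, 700L), end = c(599L, 1100L),
                           stringsAsFactors = FALSE))
  dom_scores <- score_units(v, by = "domain", domains = doms)
  expect_lte(dom_scores$percentile[dom_scores$unit_id == "DFOC"],
             quantile(dom_scores$percentile, 0.1))
})

test_that("converting tolerated variants to damaging never relaxes a unit's percentile", {
  set.seed(31)
  n_units <- 40L
  tot <- sample(30:120, n_units, replace = TRUE)
  dmg <- rbinom(n_units, tot, 0.2)
  v <- make_predictions(tot, dmg)
  base <- score_units(v, by = "gene")
  for (g in sample(unique(v$gene_id), 5)) {
    idx <- which(v$gene_id == g & v$label == "TOLERATED")
    k <- min(5L, length(idx))
    if (k == 0L) next
    v2 <- v
    v2$label[idx[seq_len(k)]] <- "DAMAGING"
    bumped <- score_units(v2, by = "gene")
    expect_lte(bumped$percentile[bumped$unit_id == g],
               base$percentile[base$unit_id == g] + 1e-9)
  }
})

test_that("damaging fractions reproduce the printed worked percentages", {
  expect_equal(damaging_fraction(720, 426)$display, 59L)
  expect_equal(damaging_fraction(237, 34)$display, 14L)
  expect_equal(damaging_fraction(538, 538 - 149)$display, 72L)
  expect_equal(damaging_fraction(100, 0)$display, 0L)
  expect_equal(damaging_fraction(720, 426)$percent, 100 * 426 / 720)
  # half-away-from-zero display rounding
  expect_equal(damaging_fraction(200, 101)$display, 51L)
  expect_equal(damaging_fraction(8, 1)$display, 13L)
  expect_error(damaging_fraction(0, 0), "undefined")
})
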