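# Independent oracles used across the suite. Each is deliberately written
# from the definition, not by calling the implementation path it checks.

# Externally studentized residuals by explicit leave-one-out refits: drop
# unit i, refit, standardize the held-out prediction error.
loo_studentized <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    s_i <- summary(fit_i)$sigma
    pred <- coef(fit_i)[1] + coef(fit_i)[2] * x[i]
    xi <- x[-i]
    # variance of the prediction error at a new point x_i
    se <- s_i * sqrt(1 + 1 / (n - 1) + (x[i] - mean(xi))^2 / sum((xi - mean(xi))^2))
    (y[i] - pred) / se
  }, numeric(1))
}

# OLS slope/intercept from the normal equations, written out by hand.
normal_equations <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}

# AUC as the probability that a random positive out-ranks a random negative,
# by exhaustive pair comparison (ties count 1/2).
pairwise_auc <- function(score_pos, score_neg) {
  tot <- 0
  for (p in score_pos) for (q in score_neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(score_pos) * length(score_neg))
}

# Upper-tail hypergeometric by exhaustive enumeration of all size-n draws
# from a genome of N genes with K annotated.
hyper_enum <- function(k, K, n, N) {
  genome <- c(rep(1, K), rep(0, N - K))
  draws <- combn(N, n)
  mean(colSums(matrix(genome[draws], nrow = n)) >= k)
}

# Two-sided Mann-Whitney p by enumeration, with U computed from the
# pair-count definition (#{x > y} + 0.5 #{x == y}) rather than rank sums.
mwu_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  mu <- n * m / 2
  idx <- combn(n + m, n)
  stats <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(stats - mu) >= abs(u_obs - mu) - 1e-9)
}

# Write a data.frame as the TSV dialect the readers expect.
write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small deterministic prediction table: n variants per gene, the first
# n_damaging of each labelled DAMAGING.
make_predictions <- function(n_total, n_damaging, genes = sprintf("G%03d", seq_along(n_total))) {
  do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(variant_id = sprintf("%s_v%d", genes[i], seq_len(n_total[i])),
               gene_id = genes[i], protein_id = paste0("P", genes[i]),
               protein_pos = seq_len(n_total[i]),
               label = c(rep("DAMAGING", n_damaging[i]),
                         rep("TOLERATED", n_total[i] - n_damaging[i])),
               score = 0, stringsAsFactors = FALSE)
  }))
}

# Scores table with prescribed studentized residuals (ascending = intolerant).
make_scores <- function(studentized, ids = sprintf("G%03d", seq_along(studentized))) {
  pct <- to_percentiles(setNames(studentized, ids))
  out <- data.frame(unit_id = pct$unit_id, n_total = 10L, n_damaging = 5L,
                    residual = pct$studentized, studentized = pct$studentized,
                    rank = pct$rank, percentile = pct$percentile,
                    stringsAsFactors = FALSE)
  class(out) <- c("intol_scores", "data.frame")
  out
}
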