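# Sub-gene statistics: the probability of observing k of n mutations inside
# a domain under a uniform per-residue mutation rate (binomial upper tail at
# p0 = domain_len / protein_len), the 10-residue-bin positional fold-change
# profile within a domain, and in/near/outside flags with residue distances.

#' Mutation-clustering probability under a uniform mutation rate
#'
#' With n mutations falling uniformly over a protein of `protein_len`
#' residues, the chance that at least k land in a domain of `domain_len`
#' residues is the binomial upper tail at p0 = domain_len / protein_len:
#' \eqn{\sum_{j=k}^{n} \binom{n}{j} p_0^j (1-p_0)^{n-j}}.
#'
#' @param n total mutations observed on the protein.
#' @param k mutations observed inside the domain (k <= n).
#' @param domain_len domain length in residues.
#' @param protein_len protein length in residues (>= domain_len).
#' @return list of class `cluster_probability`: `n_mutations`, `k_in_domain`,
#'   `domain_len`, `protein_len`, `p0`, `p_value`.
#' @export
clustering_pvalue <- function(n, k, domain_len, protein_len) {
  if (k > n) stop("clustering_pvalue: k must not exceed n", call. = FALSE)
  if (k < 0 || n < 0) stop("clustering_pvalue: counts must be non-negative", call. = FALSE)
  if (domain_len < 1 || protein_len < 1 || domain_len > protein_len)
    stop("clustering_pvalue: need 1 <= domain_len <= protein_len", call. = FALSE)
  p0 <- domain_len / protein_len
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  structure(list(n_mutations = n, k_in_domain = k, domain_len = domain_len,
                 protein_len = protein_len, p0 = p0, p_value = p),
            class = "cluster_probability")
}

#' @export
print.cluster_probability <- function(x, ...) {
  cat(sprintf("Domain mutation clustering: %d/%d mutations in a %d/%d-residue domain (p0 = %.4g), P = %.3g\n",
              x$k_in_domain, x$n_mutations, x$domain_len, x$protein_len, x$p0, x$p_value))
  invisible(x)
}

#' Pooled clustering probability across genes with unequal lengths
#'
#' When the n mutations come from several genes whose domain/protein length
#' ratios differ, each mutation has its own in-domain probability and the
#' tail of the total in-domain count follows a Poisson-binomial law, computed
#' exactly by dynamic programming.
#'
#' @param k observed in-domain count.
#' @param p0 numeric vector, one in-domain probability per mutation.
#' @return upper-tail P(X >= k).
#' @export
clustering_pvalue_pooled <- function(k, p0) {
  n <- length(p0)
  if (k > n || k < 0) stop("clustering_pvalue_pooled: need 0 <= k <= length(p0)", call. = FALSE)
  if (any(p0 < 0) || any(p0 > 1)) stop("clustering_pvalue_pooled: probabilities must be in [0, 1]", call. = FALSE)
  pmf <- 1
  for (p in p0) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  sum(pmf[(k + 1L):(n + 1L)])
}

#' Positional fold-change profile of mutations within a domain
#'
#' Bins the domain into consecutive `bin_width`-residue windows (the last
#' bin may be shorter; its true width is used for its expected count) and
#' reports observed counts, the uniform-rate expectation
#' `total * width / domain_len`, and their ratio.
#'
#' @param positions 1-based residue indices within the domain (non-empty).
#' @param domain_len domain length in residues.
#' @param bin_width residues per bin (default 10).
#' @return data.frame with `start`, `end`, `observed`, `expected`,
#'   `fold_change`.
#' @export
positional_profile <- function(positions, domain_len, bin_width = 10) {
  if (length(positions) == 0L) stop("positional_profile: empty position list", call. = FALSE)
  if (bin_width < 1) stop("positional_profile: bin_width must be >= 1", call. = FALSE)
  bad <- positions < 1 | positions > domain_len | positions != floor(positions)
  if (any(bad))
    stop(sprintf("positional_profile: position %s outside [1, %d]", positions[bad][1L], domain_len),
         call. = FALSE)
  starts <- seq(1L, domain_len, by = bin_width)
  ends <- pmin(starts + bin_width - 1L, domain_len)
  bin_of <- findInterval(positions, starts)
  observed <- tabulate(bin_of, nbins = length(starts))
  width <- ends - starts + 1L
  expected <- length(positions) * width / domain_len
  data.frame(start = starts, end = ends, observed = observed,
             expected = expected, fold_change = observed / expected)
}

#' Classify variants as inside, near, or outside annotated domains
#'
#' A variant is `IN` if its residue lies within any interval of its protein;
#' otherwise `NEAR` with the residue distance to the closest interval
#' boundary. Variants on proteins with no annotated interval are `OUTSIDE`
#' (distance `NA`); variants without a position are excluded with a warning.
#'
#' @param variants data.frame from [read_predictions()] (needs `protein_id`,
#'   `protein_pos`).
#' @param domains data.frame from [read_domains()].
#' @return data.frame with `variant_id`, `protein_id`, `protein_pos`,
#'   `status` (IN/NEAR/OUTSIDE), `distance`, `nearest_domain`.
#' @export
domain_overlap_flags <- function(variants, domains) {
  has_pos <- !is.na(variants$protein_id) & !is.na(variants$protein_pos)
  if (any(!has_pos))
    warning(sprintf("domain_overlap_flags: excluded %d variant(s) without protein position", sum(!has_pos)))
  v <- variants[has_pos, , drop = FALSE]
  by_prot <- split(domains, domains$protein_id)
  rows <- lapply(seq_len(nrow(v)), function(i) {
    iv <- by_prot[[v$protein_id[i]]]
    pos <- v$protein_pos[i]
    if (is.null(iv) || nrow(iv) == 0L)
      return(data.frame(variant_id = v$variant_id[i], protein_id = v$protein_id[i],
                        protein_pos = pos, status = "OUTSIDE", distance = NA_real_,
                        nearest_domain = NA_character_, stringsAsFactors = FALSE))
    inside <- pos >= iv$start & pos <= iv$end
    if (any(inside)) {
      data.frame(variant_id = v$variant_id[i], protein_id = v$protein_id[i],
                 protein_pos = pos, status = "IN", distance = 0,
                 nearest_domain = iv$domain_id[which(inside)[1L]], stringsAsFactors = FALSE)
    } else {
      d <- pmin(abs(pos - iv$start), abs(pos - iv$end))
      j <- which.min(d)
      data.frame(variant_id = v$variant_id[i], protein_id = v$protein_id[i],
                 protein_pos = pos, status = "NEAR", distance = d[j],
                 nearest_domain = iv$domain_id[j], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
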