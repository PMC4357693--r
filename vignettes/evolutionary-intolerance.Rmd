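---
title: "Evolutionary intolerance scoring: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary intolerance scoring: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evintol)
```

## The model

A gene that cannot tolerate missense mutation should show an excess of
predicted-damaging variants relative to its total mutational load. `evintol`
operationalizes this in four steps:

1. **Aggregate.** Each scored variant carries a DAMAGING/TOLERATED label
   from a conservation-based predictor (consumed as given — the predictor
   itself is out of scope). Per unit (gene, or protein domain via interval
   intersection) we count total variants $n_i$ and damaging variants $d_i$.
2. **Regress.** OLS of $n_i$ on $d_i$ with intercept. The fit absorbs the
   dominant nuisance structure: long, SNP-dense genes have more of both
   kinds of variant.
3. **Studentize.** The score is the externally studentized (deletion)
   residual $r_i = e_i / (s_{(i)}\sqrt{1-h_i})$, computed in closed form
   from the full-fit residual sum of squares. Deletion residuals are the
   standard regression-diagnostic choice: a gene with an extreme excess does
   not inflate the very error estimate used to judge it.
4. **Rank.** Units are sorted ascending by $r_i$ (ties get average ranks)
   and `percentile = 100 * rank / N`. Negative residual ⇒ damaging excess ⇒
   low percentile ⇒ intolerant; the most intolerant unit of a 100+-unit
   ranking lands in the first percentile, and the conventional working
   cutoff is the 25th percentile.

### Regression orientation

Both orientations of the load regression appear in the literature and
differ only in sign convention. The default here regresses **total on
damaging** so that intolerance is a *negative* residual and low percentiles
are bad, with no sign flip anywhere downstream. The reversed orientation
(`orientation = "damaging_on_total"`) is available; it ranks by descending
residual so the two orientations agree on who is intolerant.

### Key assumptions

* The damaging/tolerated labels are exchangeable across genes — systematic
  predictor bias by gene class propagates directly into the score.
* A single linear trend relates load to damaging count; there is no
  per-gene mutation-rate model (contrast constraint-score approaches that
  calibrate expected mutation counts per gene).
* Units with at least one scored variant all enter the fit; no
  minimum-count filter is applied. Very low-count units are protected from
  over-interpretation by studentization (their residuals are small in units
  of $s_{(i)}$), not by exclusion.

## Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `orientation` | total_on_damaging | `score_units` | sign convention of the score |
| `type` | external | `studentize` | deletion vs internal studentization |
| TPM threshold | 100 (strict >) | `expressed_genes` | "reliably expressed" in a context |
| percentile cutoff | 25 | benchmarking/context | working definition of "intolerant" |
| comparator | `<=` benchmark, `<` context | `recovery_at`, `fold_enrichment` | both phrasings are in use; each op documents its own and accepts an override |
| `min_combined`, `min_experimental` | 500, 0 (both strict) | `filter_edges` | high-confidence experimentally supported edges |
| MCODE `vwp`, `degree_cutoff`, haircut, fluff, `max_depth` | 0.2, 2, on, off, 100 | `mcode_clusters` | the published defaults of the algorithm |
| `background` | other_clustered | `cluster_intolerance_tests` | rank-test background population |
| `min_members` | 10 | `cluster_intolerance_tests` | smallest cluster worth testing |
| `alpha` | 0.05 | `cluster_intolerance_tests` | family-wise error before Bonferroni division |

Percentile formula: `100 * rank / N` (worst unit exactly 100; alternatives
such as `(rank-1)/N` differ by O(1/N) and are not exposed). Displayed
percentages round half-away-from-zero to integers.

## Numerical choices and degenerate inputs

* **Degenerate fits.** Fewer than 3 units, an all-constant predictor, or a
  perfect line (zero residual variance) are hard errors — a studentized
  residual is meaningless in each case. External studentization additionally
  needs ≥ 4 units.
* **Leverage ≈ 1.** Units with $1-h_i \le 10^{-10}$ get `NA` scores with a
  warning rather than an unstable division.
* **Ties.** Average ranks everywhere, which keeps the ranking invariant
  under input permutation. The Mann–Whitney test uses midranks, enumerating
  the exact permutation distribution when both samples have ≤ 8
  observations (exact even under ties, which `stats::wilcox.test` does not
  provide) and a tie- and continuity-corrected normal approximation
  otherwise; the two branches agree within 0.01 at $n=m=9$.
* **Binomial clustering tail** uses `stats::pbinom` (`lower.tail = FALSE`),
  which is accurate far into the tail; a Poisson–binomial variant
  (`clustering_pvalue_pooled`, exact dynamic programming) covers mutations
  pooled across genes with unequal domain/protein length ratios. For the
  13-mutation/10-in-domain configuration at $p_0 = 0.1$ the model gives
  $P \approx 2.1\times10^{-8}$; this is the value the stated null actually
  produces, and the package treats the null's definition — not any
  particular printed figure — as the specification.
* **MCODE determinism.** Vertex-weight ties are broken by lexicographic
  node id (the published algorithm leaves this open). Only positive-weight
  vertices seed clusters: a zero-weight seed would set the inclusion
  threshold to zero and absorb its whole component, which contradicts the
  algorithm's intent of growing from locally dense vertices. Haircut is the
  2-core of the candidate cluster (iterated removal of singly connected
  members); the fluff expansion, off by default in the original tool, is
  not implemented.
* **Bonferroni divisor** = the number of clusters actually tested (those
  with ≥ `min_members` scored members), the only divisor that is
  well-defined from the data at hand.
* **Id mismatches.** Scored genes absent from an expression matrix count as
  not expressed; benchmark-set genes never scored are dropped and reported,
  not counted as misses. Both are logged.
* **Atomic output.** The CLI writes to a temp file and renames, so a killed
  run never leaves a truncated table.

## What the synthetic generators emulate

`simulate_variants` plants intolerant genes by raising their per-variant
damaging probability (0.15 background → 0.6 planted, 30–300 variants/gene,
1000 genes by default). These rates reproduce the magnitude of the signal
seen in heavily mutated disease genes, where roughly 60% of documented SNVs
are called damaging against a background nearer 15–20%. What the generator
deliberately does **not** model: mutation-rate heterogeneity along the
genome, linkage between variants, allele frequencies, and predictor error
correlated with gene class. Passing recovery tests therefore demonstrates
that the statistical machinery isolates a planted damaging-rate excess — not
that any particular real gene list will be recovered at the same rate.

`simulate_expression` gives each gene a base TPM drawn away from the
100-TPM decision boundary (low 5, high 150–450 by default, ±10% per-sample
jitter), so the planted expressed sets are recovered exactly at the default
threshold; it does not model count noise, library-size variation, or
correlated samples.

`simulate_network` overlays a planted clique on an Erdős–Rényi background
(300 nodes, edge probability 0.02, clique of 15), shifts the planted
members' residuals by −2 SD, and draws edge scores so the documented filter
retains exactly the intended graph (plus decoy edges that must be dropped).
Real interactomes are heavy-tailed and modular far beyond this null; the
fixture tests cluster *detection and testing machinery*, not biological
realism.

`simulate_tissue_study` couples the generators into the scenario where
context filtering pays off: 150 strongly intolerant competitor genes
(damaging probability 0.5) expressed only outside the target tissue, 30
moderately intolerant disease genes (0.22) expressed only inside it at
120–450 TPM, and a half-ubiquitous background (base 300–900 TPM). The TPM
threshold sweep over {0, 50, 100, 200, 500} is then unimodal by
construction: at 0 nothing is filtered (fold exactly 1), at 50–200 the
competitors vanish and the disease genes rise into the top quartile
(fold > 1), and at 500 the filter swallows the disease genes themselves.
The competitor/disease tier sizes and rates were fixed once to make each
regime of the sweep non-empty at the default study size; they are study
conditions, not tuning knobs.

With few detected clusters, the "other clusters" rank-test background is
dominated by the planted cluster itself, which can make a null cluster look
significantly tolerant by contrast. That is a property of the background
definition, not an error; the planted-signal checks therefore use
`background = "all_scored"`, and both options are exposed.

## Problem sizes

The test suite runs the full pipeline at 1000 genes (~165k variants), the
interactome analysis at 300 nodes, exact rank-test enumeration up to
$8+8$ observations, a $10^7$-draw Monte-Carlo check of the binomial tail,
and 2000 null simulations for the rank test's type-I error; the whole suite
completes in well under a minute on one core, and `scripts/acceptance.R`
in about two.

## Known limitations

* The score inherits every bias of the upstream variant classifier; genes
  with few scored variants are rankable but weakly informative.
* Percentiles are relative to the scored universe — changing the input
  corpus changes every percentile, so cross-corpus comparisons of absolute
  percentiles are not meaningful.
* Context re-ranking never refits the regression; it re-indexes the global
  ranking. This is by design (the expression filter is a lens, not a new
  model), but it means a gene's residual ignores tissue-specific mutation
  patterns.
* The clustering null assumes a uniform per-residue mutation rate within a
  protein; regional mutability differences will inflate apparent
  clustering.
* MCODE cluster membership is greedy and order-dependent in principle; the
  documented tie-breaks make it reproducible, but small score perturbations
  can move boundary nodes between clusters.
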