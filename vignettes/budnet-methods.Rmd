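---
title: "Methods: screening tumor-budding biomarkers on small imbalanced cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening tumor-budding biomarkers on small imbalanced cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budnet)
```

## The problem

Tumor budding (TB) — single cancer cells or clusters of up to four cells at
the invasive front — is graded from stained sections as low (0–4 buds per
high-power field), intermediate (5–9) or high (≥10); `categorize_budding()`
encodes this convention. Cohorts annotated this way are small and
imbalanced (the design this package is built around has 12 high-TB and 3
low-TB samples), which is hostile territory for mean-based tests: with
three samples in one class, a single noisy library can dominate the group
mean. `budnet` therefore screens genes two ways — a parametric test on
means and a distribution-free mutual-information score — keeps only genes
found by both, and then uses a protein-interaction network to expand this
small, high-confidence seed set into a candidate module large enough for
pathway-level interpretation.

## Preprocessing

Counts may arrive at probe level with several probes per gene symbol.
`collapse_probes()` keeps, for each symbol, the probe with the largest mean
raw count, verbatim — selection, not summation, so one badly attenuated
probe cannot dilute a well-measured one. The mean is taken on raw counts
because collapse precedes normalization in the workflow; ties break toward
the lexicographically smallest probe id so the pipeline is deterministic.

`size_factors()` is the median-of-ratios estimator: factor_j =
median over genes of count_gj / geometric-mean_g, restricted to genes with
positive counts in every sample. One caveat is stated here because it is a
genuine property of the method, not an implementation detail: the reference
geometric means come from the same matrix, so the factors are defined only
up to one global depth constant. Rescaling sample depths changes all
normalized values by a single common multiplier and nothing else; every
downstream statistic (fold changes, MI after binning, correlations, PCA,
silhouettes) is invariant to that multiplier.

## Differential expression

The test is a deliberately minimal two-group negative-binomial Wald test.
Per gene, with size-factor offsets s_j and NB2 variance μ + αμ²:

* **Dispersion** (`estimate_dispersion()`): method of moments on the
  normalized scale, α̂ = max(0, (s² − μ̄)/μ̄²) per class, pooled with
  degrees-of-freedom weights, floored at 1e-8 (the floor keeps the fitted
  information matrix finite for genes whose moment estimate is exactly
  zero). A `"trend"` mode replaces gene-wise values with a fitted
  α(μ) = a/μ + b curve; the gene-wise mode is the default because with 15
  samples the trend fit is itself noisy and the moment estimator's bias is
  absorbed by the fold-change filter below.
* **Fit** (`run_diffexp()`): each group's log mean is obtained by Newton
  scoring of the NB log-likelihood at fixed dispersion (log link, offsets
  log s_j); logFC = (b_high − b_low)/ln 2, its standard error from the
  expected information, stat = logFC/lfcSE, and a two-sided standard-normal
  tail for the p-value. No fold-change shrinkage is applied. A gene with an
  all-zero class gets the pseudo-mean 0.5/mean(s_j) for that class and a
  flag; all-zero genes are excluded and do not count toward the
  Benjamini–Hochberg denominator.
* **Filter** (`filter_degs()`): adj. p < 0.05 and |log2FC| > 1.5, both
  strict. At n = 15 the Wald test is mildly anti-conservative; the test
  suite bounds its null size (fraction of null genes with p < 0.05 within
  [0.025, 0.10], median over 20 simulations of 2000 genes) rather than
  pretending it is exact, and the |log2FC| filter does most of the work of
  keeping the false-discovery rate of the final list low.

This is intentionally not a re-implementation of any full production DE
engine (no Cox–Reid adjustment, no outlier replacement, no independent
filtering): the package's subject is the pipeline logic, and the two-group
contract is fully specified by the simple model above.

## Mutual information

`mi_score()` computes MI(X, Y) = H(X) + H(Y) − H(X, Y) in natural-log
units between a gene's discretized normalized expression and the binary
class. Nats are forced by the headline constant: with class frequencies
12/15 and 3/15, H(Y) = −(0.8 ln 0.8 + 0.2 ln 0.2) = 0.5004 nats, and no
gene can exceed that ceiling. A gene whose bins are pure in class attains
it exactly, so the ceiling doubles as a certificate of perfect separation.

Discretization is a configuration knob, never hard-coded: `equal_width`
(default), `equal_frequency`, or `distinct`. The default bin count is
Sturges-like, min(⌈log2 n⌉ + 1, distinct values) — 5 bins at n = 15.
`equal_frequency` assigns equal-count bins from average ranks rather than
literal quantile edges: on heavily tied data (a separator gene is 0 in one
entire class) duplicate quantile edges would collapse bins and destroy the
separation the method is supposed to detect, whereas rank binning keeps
tied values together and never produces a degenerate single bin for
two-valued data. Selection (`select_top_mi()`) defaults to the maximal tie
set with tolerance 1e-9, because at n = 15 the score is coarse and the top
of the ranking is a plateau, not a point; `top_k` with boundary-tie
inclusion is available.

## Network diffusion

Seeds are the sorted intersection of the DE list and the MI tie set
(`build_seed_set()`); seeds missing from the network are reported and
dropped from the indicator. With W the weighted adjacency (STRING combined
scores in (0,1], strict threshold > 0.4 at read time), D = diag(rowSums W)
and L = D − W, scores solve (I + αL) s = y (`diffuse()`). Two structural
facts are asserted as tests rather than assumed: the all-ones vector is a
left null vector of L, so Σs = Σy (seed mass is conserved), and I + αL is
an M-matrix, so s ≥ 0; components with no seed score exactly zero.

The system is solved by sparse Cholesky factorization (Matrix) rather than
an iterative conjugate-gradient scheme: at the scale of real interactomes
(~2 × 10⁴ nodes, ~10⁶ edges) the factorization is exact, fast, and the
contract — never materialize the dense inverse — is the same. A dense
solve serves as the independent oracle in tests at n ≤ 200.

α (unitless, default 1.0) trades locality against smoothing: α → 0 returns
the seed indicator, α → ∞ flattens scores toward uniformity (score
variance decreases in α on connected graphs, tested). There is no
principled universal value; 1.0 sits in the regime where seed
neighborhoods dominate (the planted-community locality test passes for α
in [0.1, 10]), and the parameter is exposed everywhere.

`percentile_cutoff()` reads "top q-th percentile" as a rank quota: the top
⌈(1 − q/100)·n⌉ nodes over all n network nodes, filled by non-seed nodes
by default so the result is the set of additional candidates (a 19,038-node
network at q = 99 yields exactly 191). Ties at the boundary break by node
id. The quota subtracts a 1e-9 guard before the ceiling so that exact
multiples are not bumped up by floating-point noise in 1 − q/100.

## Enrichment

`enrich()` is a local over-representation analysis over GMT collections:
hypergeometric upper tail P(X ≥ k) for overlap k between the query and
each set, both intersected with an explicit, caller-visible universe
(default: all network nodes when enriching diffusion output). Set sizes
are measured after intersection with the universe (sets of effective size
outside [10, 500] are not tested), p-values are BH-adjusted across tested
sets, rows with raw p < 0.01 (strict) are kept, and output is ordered by
gene ratio k/K then p-value. The pipeline queries the percentile
candidates together with the matched seeds, since the candidates are
defined as proteins related to the seeds and the module is interpreted as
a whole. Web-service enrichment backends use proprietary term collections
and universes; making both explicit here is what makes runs reproducible.

## Panel evaluation

`evaluate_panel()` quantifies what cluster heatmaps show visually: Pearson
correlation between sample profiles, PCA onto the first two components
(per-gene standardized, deterministic sign convention: the
largest-magnitude loading of each component is positive), and a silhouette
separation score, all on log2(x + 1) expression (the pseudocount 1 keeps
zeros finite and is the only transform parameter). For a singleton class
the within-class distance is taken as 0 — the score then reflects only the
distance to the other class — and the result is flagged; the classical
convention would assign such samples a silhouette of 0, which with a
1-sample class would mute the very comparison the score exists for.

## The synthetic cohort

`simulate_counts()` emulates the study conditions: 12 vs 3 samples,
NB counts with mean s_j·q_g (baseline log-normal around 100, matching the
few-hundred baseMean range typical of targeted panels), shared dispersion
0.1 (optionally per-gene Gamma), size factors log-uniform on [0.5, 2], 5%
of genes with planted symmetric log2 effects centered at 2.5, and 7
planted perfect separators (zero in one class, tightly clustered positive
values in the other, alternating direction like a real panel of up- and
down-regulated markers). The separator construction guarantees
non-overlapping normalized ranges, hence the MI ceiling, under every
supported discretization. `simulate_network()` provides Barabási–Albert
graphs (m isolated initial nodes, first attachment to all of them, then
preferential attachment: exactly m(n − m) edges, connected) or stochastic
block models reduced to their largest component, with confidence weights
in (0.4, 1]; `simulate_pathways()` plants sets built from the seeds
outward (seeds, then 1-hop, then 2-hop neighbors, ≥70% of members within
two hops) plus uniform decoys. All randomness flows from one integer seed
through isolated RNG scopes; the global RNG state is never touched.

What the generator does **not** emulate: probe-level attenuation and FFPE
degradation, correlated gene-gene expression beyond the class effect,
hub-biased degree-expression coupling, or realistic pathway overlap
structure. Passing tests therefore certify the pipeline's statistical
contracts under its own model assumptions, not performance on any real
cohort.

## Problem sizes and numerical choices

The test suite runs at desk scale: worked examples are exact
(3-node kernel, 2×2 size factors, 4-value BH step-up, hypergeometric
enumeration at N ≤ 25 to 1e-12); statistical properties use 2000-gene
12-vs-3 simulations with 20 replicates (DE recovery: median observed FDR
≤ 0.10 and power ≥ 0.5; null size bounds), 20 replicate seeds of the full
pipeline for planted-seed recovery, 200 replicates for the enrichment
null, and 100 replicates for panel comparisons. Dispersion floor 1e-8;
Newton steps clamped to ±5 with convergence at |step| < 1e-12; diffusion
residual tolerance 1e-8 with negative scores beyond −1e-10 treated as
errors; MI tie tolerance 1e-9.

## Known limitations

* The Wald p-values are asymptotic and the cohort is tiny; they rank genes
  well but should not be read as calibrated probabilities, which is why
  the DEG definition includes the fold-change filter.
* The MI screen's tie set grows as samples shrink (many genes separate
  12-vs-3 by chance); it is a recall-oriented filter whose precision comes
  from the intersection with the DE list.
* Probe collapse by maximum mean discards within-gene probe replication
  rather than modeling it.
* The diffusion α and the percentile are analysis choices, not estimated
  quantities; conclusions should be checked for stability across a small
  grid of both.
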