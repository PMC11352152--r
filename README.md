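# budnet

Tumor budding — isolated cancer cells or clusters of up to four cells at
the invasive tumor front — is a prognostic marker in breast cancer, graded
low (0–4 buds), intermediate (5–9) or high (≥10 buds per high-power field).
`budnet` implements a biomarker-discovery pipeline for exactly the kind of
cohort where this question arises in practice: a gene × sample count matrix
with very few, heavily imbalanced samples (the motivating design is 12
high-TB vs 3 low-TB cases), where mean-based tests alone are fragile.

The pipeline combines two complementary screens and a network step:

1. **Differential expression** — a deliberately simple two-group
   negative-binomial Wald test: median-of-ratios size factors,
   method-of-moments gene-wise dispersion (NB2 variance μ + αμ²), per-group
   log-mean fit by Newton scoring, Wald statistic on
   log2FC = log2(x̄_high / x̄_low), Benjamini–Hochberg adjustment, and the
   filter adj. p < 0.05, |log2FC| > 1.5.
2. **Mutual information** — MI(X, Y) = H(X) + H(Y) − H(X, Y) in nats
   between each gene's discretized normalized expression X and the binary
   TB class Y. With 12 vs 3 samples the ceiling is
   H(Y) = −(0.8 ln 0.8 + 0.2 ln 0.2) = 0.5004 nats, attained exactly by any
   gene that perfectly separates the classes; the screen keeps the
   top-scoring tie set.
3. **Network diffusion** — the intersection of the two gene lists seeds a
   regularized-Laplacian diffusion over a STRING-style weighted
   protein–protein interaction network (combined score > 0.4):
   S = (I + αL)⁻¹ y with L = D − W, solved as a sparse SPD system. The top
   ⌈(1 − q/100)·n⌉ non-seed nodes at the q-th percentile (default 99)
   become candidate proteins, which are interpreted with a local
   hypergeometric over-representation test against GMT gene sets
   (effective set size 10–500, p < 0.01, ranked by gene ratio k/K).

A synthetic-data module generates NB count matrices with planted
differentially expressed genes and planted perfect separators, scale-free
or block-model networks, and pathway collections enriched around planted
seeds, so the whole analysis is testable offline.

## Worked example

```r
library(budnet)

res <- run_pipeline(list(simulate = list(), rng_seed = 11),
                    out_dir = "budnet_run")
length(res$degs)                     # genes passing adj.p < 0.05, |log2FC| > 1.5
max(res$mi_table$mi_score)           # MI ceiling reached by separators
length(res$seeds$genes)              # DE ∩ MI intersection
head(res$enrichment[, c("set_name", "overlap_k", "set_size_K",
                        "pvalue", "gene_ratio")], 3)
res$evaluation
```

On the default synthetic cohort (2000 genes, 12 vs 3 samples, 5% planted
effects at |log2FC| ≈ 2.5, dispersion 0.1, 500-node scale-free network,
seed 11) this prints:

```
[1] 99
[1] 0.5004024
[1] 89
  set_name overlap_k set_size_K       pvalue gene_ratio
1   SET001         9         18 3.331857e-07  0.5000000
2   SET002         7         18 6.694307e-05  0.3888889
3   SET003         7         30 2.353942e-03  0.2333333
bud_panel_eval: 89 genes, separation score 0.783, PC1 82.2% / PC2 2.7% variance
```

All 7 planted separator genes sit in the seed list (the other members are
genes that separate 12-vs-3 classes by chance — with 15 samples, tie sets
at the MI ceiling are large, which is exactly why the DE intersection
matters), the maximal MI equals the class entropy 0.5004, and all three
pathway sets planted around the seeds are recovered with the largest gene
ratios. Every stage is also exported on its own (`read_counts`,
`collapse_probes`, `size_factors`, `run_diffexp`, `mi_table`,
`build_seed_set`, `diffuse`, `percentile_cutoff`, `enrich`,
`evaluate_panel`, `simulate_*`) for use outside `run_pipeline`; see the
vignette in `vignettes/` for the methods account.

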