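# Shared fixture builders; everything is generated in code at test time.

# unweighted path graph 1-2-3 (unit confidences)
path3_network <- function() {
  bud_network(data.frame(from = c("n1", "n2"), to = c("n2", "n3"),
                         weight = c(1, 1)))
}

# connected Erdos-Renyi graph with random confidence weights in (0.4, 1]
random_connected_network <- function(n, p = 0.08, seed = 1) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
    ed <- as.data.frame(igraph::as_edgelist(g, names = FALSE))
    nm <- sprintf("v%03d", seq_len(igraph::vcount(g)))
    bud_network(data.frame(from = nm[ed$V1], to = nm[ed$V2],
                           weight = 0.4 + runif(nrow(ed)) * 0.6),
                nodes = nm)
  })
}

# independently assembled dense I + alpha*L, used as the diffusion oracle
dense_system <- function(network, alpha) {
  nodes <- network$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(network$edges))) {
    i <- network$edges$from[r]; j <- network$edges$to[r]
    W[i, j] <- W[i, j] + network$edges$weight[r]
    W[j, i] <- W[j, i] + network$edges$weight[r]
  }
  diag(n) + alpha * (diag(rowSums(W)) - W)
}

# write a small count matrix TSV (optionally with a gene-symbol column)
write_counts_tsv <- function(counts, symbols = NULL,
                             path = withr::local_tempfile(fileext = ".tsv",
                               .local_envir = parent.frame())) {
  header <- c("probe_id", if (!is.null(symbols)) "gene_symbol",
              colnames(counts))
  rows <- vapply(seq_len(nrow(counts)), function(i)
    paste(c(rownames(counts)[i], if (!is.null(symbols)) symbols[i],
            counts[i, ]), collapse = "\t"), character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

write_lines_tmp <- function(lines,
                            path = withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# 12 high / 3 low annotation matching the motivating cohort layout
cohort_samples <- function(n_high = 12, n_low = 3) {
  bud_samples(sprintf("S%02d", seq_len(n_high + n_low)),
              c(rep("high", n_high), rep("low", n_low)))
}

# brute-force hypergeometric upper tail by full enumeration of the support
enum_hyper_tail <- function(k, K, n, N) {
  i <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(probs[i >= k])
}
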