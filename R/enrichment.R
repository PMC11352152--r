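# Local hypergeometric over-representation analysis over GMT gene sets,
# standing in for web-service enrichment so runs are reproducible offline.

#' Hypergeometric upper-tail p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least k members of a K-gene set when sampling n genes from a universe of
#' N without replacement.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return p-value (vectorized over its arguments).
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0))
    stop("arguments must be nonnegative")
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("inconsistent hypergeometric arguments: need k <= min(K, n) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene ratio
#'
#' Overlap between the query and a pathway divided by the pathway's size:
#' the dot-plot x-axis of over-representation summaries.
#'
#' @param k overlap count.
#' @param K pathway size (>= 1).
#' @return k / K.
#' @export
gene_ratio <- function(k, K) {
  if (any(K < 1)) stop("pathway size K must be >= 1")
  if (any(k < 0) || any(k > K)) stop("need 0 <= k <= K")
  k / K
}

#' Over-representation analysis of a gene list
#'
#' Each gene set is intersected with the declared universe; sets whose
#' effective size falls within `[min_size, max_size]` are tested with the
#' hypergeometric upper tail, adjusted across tested sets by
#' Benjamini-Hochberg, and rows with raw p-value strictly below `alpha`
#' are returned sorted by gene ratio (descending) then p-value.
#'
#' @param query character vector of genes of interest; genes outside the
#'   universe are dropped with a warning.
#' @param db [bud_pathways].
#' @param universe character vector of background genes (deduplicated).
#' @param min_size,max_size effective set-size window (defaults 10, 500).
#' @param alpha raw p-value threshold (default 0.01, strict).
#' @return data.frame `set_name`, `overlap_k`, `set_size_K`, `query_n`,
#'   `universe_N`, `pvalue`, `padj`, `gene_ratio`, `overlap_genes`
#'   (comma-separated).
#' @export
enrich <- function(query, db, universe, min_size = 10, max_size = 500,
                   alpha = 0.01) {
  stopifnot(inherits(db, "bud_pathways"))
  if (min_size > max_size) stop("min_size must be <= max_size")
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after restriction to the universe")
  if (!length(db$sets)) stop("empty pathway collection")
  members <- lapply(db$sets, intersect, universe)
  K <- lengths(members)
  testable <- which(K >= min_size & K <= max_size)
  if (!length(testable)) {
    return(data.frame(set_name = character(), overlap_k = integer(),
                      set_size_K = integer(), query_n = integer(),
                      universe_N = integer(), pvalue = numeric(),
                      padj = numeric(), gene_ratio = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  }
  n <- length(query)
  N <- length(universe)
  ov <- lapply(members[testable], intersect, query)
  k <- lengths(ov)
  p <- hypergeom_pvalue(k, K[testable], n, N)
  padj <- adjust_bh(p)
  out <- data.frame(set_name = names(db$sets)[testable],
                    overlap_k = k, set_size_K = K[testable],
                    query_n = n, universe_N = N,
                    pvalue = p, padj = padj,
                    gene_ratio = gene_ratio(k, K[testable]),
                    overlap_genes = vapply(ov, paste, character(1L),
                                           collapse = ","),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$pvalue < alpha, , drop = FALSE]
  out <- out[order(-out$gene_ratio, out$pvalue, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
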