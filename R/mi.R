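# Mutual-information screening of genes against the binary tumor-budding
# class. All entropies are in natural-log units (nats): with 12 high and 3
# low samples the class entropy — and hence the ceiling any single gene can
# attain — is H(12/15, 3/15) = 0.5004 nats.

#' Default bin count for discretization
#'
#' Sturges-like rule: `min(ceiling(log2(n)) + 1, number of distinct values)`.
#'
#' @param values numeric vector.
#' @return integer number of bins (at least 1).
#' @export
default_bins <- function(values) {
  n <- length(values)
  max(1L, min(ceiling(log2(max(n, 2L))) + 1L, length(unique(values))))
}

#' Discretize a continuous expression vector
#'
#' @param values per-sample numeric values.
#' @param method `"equal_width"` (uniform bin edges over the observed
#'   range), `"equal_frequency"` (equal-count bins assigned from average
#'   ranks, so tied values always share a bin and duplicate quantile edges
#'   cannot produce degenerate bins) or `"distinct"` (each unique value its
#'   own category).
#' @param n_bins number of bins for the binning methods (>= 2); ignored by
#'   `"distinct"`. Default [default_bins()].
#' @return integer vector of category codes starting at 1. A constant
#'   vector yields a single category.
#' @export
discretize <- function(values,
                       method = c("equal_width", "equal_frequency", "distinct"),
                       n_bins = default_bins(values)) {
  method <- match.arg(method)
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  if (method == "distinct")
    return(match(values, sort(unique(values))))
  if (length(unique(values)) == 1L) return(rep(1L, length(values)))
  if (n_bins < 2L) stop("n_bins must be >= 2 for binning methods")
  if (method == "equal_frequency") {
    r <- rank(values, ties.method = "average")
    codes <- pmin(pmax(ceiling(r * n_bins / length(values)), 1L), n_bins)
    return(match(codes, sort(unique(codes))))
  }
  breaks <- seq(min(values), max(values), length.out = n_bins + 1L)
  as.integer(cut(values, breaks = breaks, include.lowest = TRUE,
                 labels = FALSE))
}

#' Empirical entropy in nats
#'
#' H(X) = -sum p(x) log p(x) over the empirical category frequencies, with
#' 0 log 0 taken as 0.
#'
#' @param labels vector of category labels.
#' @return entropy in nats.
#' @export
entropy <- function(labels) {
  stopifnot(length(labels) >= 1L)
  p <- tabulate(as.integer(factor(labels)))
  p <- p[p > 0] / length(labels)
  -sum(p * log(p))
}

#' Empirical joint entropy in nats
#'
#' @param labels_x,labels_y equal-length category vectors.
#' @return joint entropy H(X, Y) in nats.
#' @export
joint_entropy <- function(labels_x, labels_y) {
  if (length(labels_x) != length(labels_y))
    stop("labels_x and labels_y must have equal length")
  entropy(paste(labels_x, labels_y, sep = "\r"))
}

#' Mutual information between a gene and the class
#'
#' MI(X, Y) = H(X) + H(Y) - H(X, Y) in nats, with X the discretized
#' normalized expression and Y the binary class. Floating-point negatives
#' are clipped at 0. A gene whose discretized categories are pure in class
#' attains the maximum MI = H(Y) exactly.
#'
#' @param gene_values per-sample normalized expression.
#' @param class_labels binary class labels (both classes must be present).
#' @param method,n_bins passed to [discretize()].
#' @return MI in nats.
#' @export
mi_score <- function(gene_values, class_labels,
                     method = c("equal_width", "equal_frequency", "distinct"),
                     n_bins = default_bins(gene_values)) {
  if (length(gene_values) != length(class_labels))
    stop("gene_values and class_labels must have equal length")
  if (length(gene_values) < 2L) stop("need at least 2 samples")
  if (length(unique(class_labels)) < 2L)
    stop("both classes must be present")
  x <- discretize(gene_values, method = method, n_bins = n_bins)
  max(0, entropy(x) + entropy(class_labels) - joint_entropy(x, class_labels))
}

#' Mutual-information score table for all genes
#'
#' @param norm [bud_norm] of normalized counts.
#' @param samples [bud_samples]; only class-labeled samples are used.
#' @param method,n_bins passed to [discretize()]; `n_bins = NULL` uses the
#'   per-gene default.
#' @return data.frame `gene`, `mi_score`, `n_bins_used`, sorted by score
#'   descending (ties by gene name).
#' @export
mi_table <- function(norm, samples,
                     method = c("equal_width", "equal_frequency", "distinct"),
                     n_bins = NULL) {
  stopifnot(inherits(norm, "bud_norm"), inherits(samples, "bud_samples"))
  method <- match.arg(method)
  lab <- samples[!is.na(samples$class_label), , drop = FALSE]
  if (!all(lab$sample_id %in% colnames(norm$values)))
    stop("sample sheet contains samples absent from the matrix")
  x <- norm$values[, lab$sample_id, drop = FALSE]
  y <- lab$class_label
  if (length(unique(y)) < 2L) stop("both classes must be present")
  scores <- numeric(nrow(x))
  bins_used <- integer(nrow(x))
  for (g in seq_len(nrow(x))) {
    nb <- if (is.null(n_bins)) default_bins(x[g, ]) else n_bins
    d <- discretize(x[g, ], method = method, n_bins = max(nb, 2L))
    scores[g] <- max(0, entropy(d) + entropy(y) - joint_entropy(d, y))
    bins_used[g] <- length(unique(d))
  }
  out <- data.frame(gene = rownames(x), mi_score = scores,
                    n_bins_used = bins_used, stringsAsFactors = FALSE)
  out[order(-out$mi_score, out$gene), , drop = FALSE]
}

#' Select top-scoring genes from an MI table
#'
#' @param tab data.frame from [mi_table()].
#' @param mode `"max_ties"` keeps every gene within `tol` of the maximum
#'   score (the "highest MI score" tie set); `"top_k"` keeps the k highest
#'   with boundary ties all included.
#' @param k number of genes for `"top_k"`.
#' @param tol tie tolerance (default 1e-9).
#' @return character vector of gene names.
#' @export
select_top_mi <- function(tab, mode = c("max_ties", "top_k"), k = NULL,
                          tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "mi_score") %in% names(tab)), nrow(tab) >= 1L)
  s <- tab$mi_score
  if (mode == "max_ties") {
    thr <- max(s) - tol
  } else {
    if (is.null(k) || k <= 0) stop("k must be a positive integer in top_k mode")
    k <- min(as.integer(k), length(s))
    thr <- sort(s, decreasing = TRUE)[k] - tol
  }
  tab$gene[s >= thr]
}
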