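# Regularized-Laplacian network diffusion. With W the weighted adjacency,
# D = diag(rowSums(W)) and L = D - W, the kernel is K = (I + alpha*L)^-1 and
# the diffusion score of a binary seed indicator y is S = K y. Since the
# all-ones vector is a left null vector of L, sum(S) = sum(y): diffusion
# conserves the seed mass. Scores are solved as the sparse SPD system
# (I + alpha*L) s = y rather than by materializing the dense inverse.

#' Build the seed set from the two screens
#'
#' Seeds are the (sorted) intersection of the differential-expression gene
#' list and the MI-selected gene list; membership in the network is checked
#' and seeds absent from it are reported and excluded from diffusion.
#'
#' @param degs character vector from [filter_degs()].
#' @param mi_genes character vector from [select_top_mi()].
#' @param network [bud_network].
#' @return Object of class `bud_seeds`: list with `genes`, `matched`,
#'   `unmatched`.
#' @export
build_seed_set <- function(degs, mi_genes, network) {
  stopifnot(inherits(network, "bud_network"))
  genes <- sort(intersect(degs, mi_genes))
  if (!length(genes)) stop("no seeds; relax thresholds")
  matched <- genes[genes %in% network$nodes]
  unmatched <- setdiff(genes, matched)
  if (length(unmatched))
    warning(length(unmatched), " seed(s) absent from the network: ",
            paste(head(unmatched, 5L), collapse = ", "))
  structure(list(genes = genes, matched = matched, unmatched = unmatched),
            class = "bud_seeds")
}

#' @export
print.bud_seeds <- function(x, ...) {
  cat(sprintf("bud_seeds: %d genes (%d in network, %d unmatched)\n",
              length(x$genes), length(x$matched), length(x$unmatched)))
  invisible(x)
}

network_adjacency <- function(network) {
  nodes <- network$nodes
  i <- match(network$edges$from, nodes)
  j <- match(network$edges$to, nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(network$edges$weight, 2L),
                       dims = c(length(nodes), length(nodes)),
                       dimnames = list(nodes, nodes))
}

#' Assemble the regularized-Laplacian system
#'
#' Builds the sparse symmetric positive-definite matrix I + alpha * L with
#' L = D - W over the network's (fixed, recorded) node order. `alpha = 0`
#' gives the identity. The dense kernel is never formed; scores come from
#' solving (I + alpha*L) s = y.
#'
#' @param network [bud_network].
#' @param alpha nonnegative diffusion strength.
#' @param weighted use edge weights (default) or unit weights.
#' @return list with `A` (sparse matrix) and `nodes` (node order).
#' @export
build_kernel_system <- function(network, alpha = 1, weighted = TRUE) {
  stopifnot(inherits(network, "bud_network"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a nonnegative scalar")
  W <- network_adjacency(network)
  if (!weighted) W@x <- rep(1, length(W@x))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  A <- Matrix::Diagonal(n = nrow(L)) + alpha * L
  list(A = A, nodes = network$nodes, alpha = alpha)
}

#' Diffuse seed scores over the network
#'
#' Solves (I + alpha*L) s = y for the binary seed indicator y and returns
#' per-node scores sorted descending, ties broken by node id. Scores are
#' nonnegative (I + alpha*L is an M-matrix) and sum to the number of
#' matched seeds; components containing no seed score exactly zero.
#'
#' @param network [bud_network].
#' @param seeds `bud_seeds` object or a character vector of seed node ids.
#' @param alpha diffusion strength (default 1).
#' @param weighted use edge weights (default TRUE).
#' @return data.frame `node`, `score`, `is_seed`, `rank`.
#' @export
diffuse <- function(network, seeds, alpha = 1, weighted = TRUE) {
  stopifnot(inherits(network, "bud_network"))
  seed_ids <- if (inherits(seeds, "bud_seeds")) seeds$matched
              else intersect(as.character(seeds), network$nodes)
  if (!length(seed_ids)) stop("at least one matched seed is required")
  sys <- build_kernel_system(network, alpha = alpha, weighted = weighted)
  y <- as.numeric(sys$nodes %in% seed_ids)
  s <- as.numeric(Matrix::solve(sys$A, y))
  resid <- max(abs(as.numeric(sys$A %*% s) - y))
  if (!is.finite(resid) || resid > 1e-8)
    stop("diffusion solve did not converge; residual norm ", resid)
  if (min(s) < -1e-10)
    stop("negative diffusion score beyond numerical tolerance")
  s <- pmax(s, 0)
  out <- data.frame(node = sys$nodes, score = s,
                    is_seed = y == 1, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Percentile cutoff on diffusion scores
#'
#' Selects the top `ceiling((1 - percentile/100) * n_total)` nodes by
#' diffusion score, where `n_total` counts every node in the network; with
#' `exclude_seeds` (default) the quota is filled by non-seed nodes only, so
#' the cutoff yields the "additional" candidate proteins. Ties at the
#' boundary are broken by node id.
#'
#' @param r data.frame from [diffuse()].
#' @param percentile percentile in (0, 100); default 99.
#' @param exclude_seeds logical, default TRUE.
#' @return character vector of candidate node ids.
#' @export
percentile_cutoff <- function(r, percentile = 99, exclude_seeds = TRUE) {
  stopifnot(all(c("node", "score", "is_seed") %in% names(r)))
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  # small tolerance so exact multiples (e.g. 1% of 500) are not bumped up
  # by floating-point noise in 1 - percentile/100
  quota <- ceiling((1 - percentile / 100) * nrow(r) - 1e-9)
  pool <- if (exclude_seeds) r[!r$is_seed, , drop = FALSE] else r
  pool <- pool[order(-pool$score, pool$node), , drop = FALSE]
  if (quota > nrow(pool)) {
    warning("quota ", quota, " exceeds available nodes; returning all ",
            nrow(pool))
    quota <- nrow(pool)
  }
  pool$node[seq_len(quota)]
}
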