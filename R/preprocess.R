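#' Collapse probe-level counts to gene level
#'
#' When several probes map to the same gene symbol, the probe with the
#' largest mean raw count is kept verbatim (selection, not summation); ties
#' are broken toward the lexicographically smallest probe id so the collapse
#' is deterministic. Collapse happens on raw counts, before normalization.
#'
#' @param m probe-level [bud_counts] with a gene symbol for every probe.
#' @return gene-level [bud_counts]; rownames are the gene symbols and the
#'   winning probe ids are kept in attribute `probe_id`.
#' @export
collapse_probes <- function(m) {
  stopifnot(inherits(m, "bud_counts"))
  if (m$level != "probe") stop("collapse_probes expects probe-level counts")
  sym <- m$gene_symbols
  if (any(is.na(sym) | !nzchar(sym))) stop("missing gene symbol")
  mu <- rowMeans(m$counts)
  ord <- order(sym, -mu, rownames(m$counts))
  keep <- ord[!duplicated(sym[ord])]
  out <- m$counts[keep, , drop = FALSE]
  probe_ids <- rownames(out)
  rownames(out) <- sym[keep]
  res <- bud_counts(out, gene_symbols = sym[keep], level = "gene")
  attr(res, "probe_id") <- stats::setNames(probe_ids, sym[keep])
  res
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes of
#' count_gj / geometric-mean_g, taken over genes whose counts are positive
#' in every sample (geometric mean > 0) — the normalization convention of
#' standard negative-binomial differential-expression workflows. Because
#' the reference geometric means come from the same matrix, the factors
#' (and hence normalized counts) are defined up to one global depth
#' constant: rescaling sample depths changes every normalized value by a
#' single common multiplier only, never the between-sample structure.
#'
#' @param m [bud_counts] (any level).
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "bud_counts"))
  lc <- log(m$counts)
  loggeo <- rowMeans(lc)
  ok <- is.finite(loggeo)
  if (!any(ok)) stop("cannot compute size factors: no gene expressed in all samples")
  sf <- apply(lc[ok, , drop = FALSE], 2L, function(col)
    exp(median(col - loggeo[ok])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("cannot compute size factors: degenerate ratios")
  sf
}

#' Normalize counts by size factors
#'
#' Divides each sample column by its size factor.
#'
#' @param m [bud_counts].
#' @param sf positive factors, one per sample (default [size_factors()]).
#' @return A [bud_norm] object.
#' @export
normalize_counts <- function(m, sf = size_factors(m)) {
  stopifnot(inherits(m, "bud_counts"))
  if (length(sf) != ncol(m$counts))
    stop("need one size factor per sample")
  if (any(sf <= 0)) stop("size factors must be positive")
  vals <- sweep(m$counts, 2L, sf, "/")
  bud_norm(vals, sf)
}

#' Categorize tumor-budding counts (ITBCC)
#'
#' Bud counts per high-power field are categorized as low (0-4 buds),
#' intermediate (5-9 buds) or high (>= 10 buds).
#'
#' @param buds nonnegative integer vector of bud counts.
#' @return character vector of levels `low` / `intermediate` / `high`.
#' @export
categorize_budding <- function(buds) {
  buds <- as.numeric(buds)
  if (any(is.na(buds)) || any(buds < 0) || any(buds != round(buds)))
    stop("bud counts must be nonnegative integers")
  ifelse(buds <= 4, "low", ifelse(buds <= 9, "intermediate", "high"))
}
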