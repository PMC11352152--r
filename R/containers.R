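#' Count matrix container
#'
#' Lightweight container for a probe- or gene-level integer count matrix,
#' in the spirit of edgeR's DGEList: a list with the count matrix, one gene
#' symbol per row, and the resolution level.
#'
#' @param counts integer matrix, rows = probes/genes, columns = samples;
#'   must have unique rownames (row ids) and unique colnames (sample ids).
#' @param gene_symbols character vector, one symbol per row. Defaults to the
#'   rownames when `level = "gene"`.
#' @param level `"probe"` or `"gene"`. At gene level the symbols must be
#'   unique.
#' @return An object of class `bud_counts`: a list with elements `counts`,
#'   `gene_symbols`, `level`.
#' @export
bud_counts <- function(counts, gene_symbols = NULL, level = c("gene", "probe")) {
  level <- match.arg(level)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (row ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate row id: ", dup)
  }
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(is.na(counts))) stop("missing values in counts")
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("non-integer count")
  if (is.null(gene_symbols)) {
    if (level == "probe")
      stop("gene_symbols required at probe level")
    gene_symbols <- rownames(counts)
  }
  gene_symbols <- as.character(gene_symbols)
  if (length(gene_symbols) != nrow(counts))
    stop("gene_symbols length must equal number of rows")
  if (level == "gene" && anyDuplicated(gene_symbols))
    stop("gene symbols must be unique at gene level: ",
         gene_symbols[duplicated(gene_symbols)][1L])
  structure(
    list(counts = counts, gene_symbols = gene_symbols, level = level),
    class = "bud_counts"
  )
}

#' @export
print.bud_counts <- function(x, ...) {
  cat(sprintf("bud_counts: %d %s rows x %d samples (%d distinct symbols)\n",
              nrow(x$counts), x$level, ncol(x$counts),
              length(unique(x$gene_symbols))))
  invisible(x)
}

#' @export
dim.bud_counts <- function(x) dim(x$counts)

#' Sample annotation constructor
#'
#' Per-sample tumor-budding level and the derived binary class used by the
#' two-group analyses (1 = high TB, 0 = low TB, NA for intermediate).
#'
#' @param sample_id character vector of unique sample ids.
#' @param tb_level character vector of levels; case-insensitive tokens
#'   `low`, `intermediate`, `high`.
#' @return A data.frame of class `bud_samples` with columns `sample_id`,
#'   `tb_level`, `class_label`.
#' @export
bud_samples <- function(sample_id, tb_level) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1L])
  tb <- tolower(trimws(as.character(tb_level)))
  bad <- setdiff(unique(tb), c("low", "intermediate", "high"))
  if (length(bad))
    stop("unknown tb_level token(s): ", paste(bad, collapse = ", "))
  cls <- ifelse(tb == "high", 1L, ifelse(tb == "low", 0L, NA_integer_))
  out <- data.frame(sample_id = sample_id, tb_level = tb,
                    class_label = cls, stringsAsFactors = FALSE)
  class(out) <- c("bud_samples", "data.frame")
  out
}

#' Protein-protein interaction network container
#'
#' Undirected weighted graph with no self-loops and no duplicate edges;
#' edge weights are interaction confidences in (0, 1].
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param nodes optional character vector of node ids; defaults to the edge
#'   endpoints. Extra isolated nodes are allowed.
#' @return An object of class `bud_network`: list with `nodes` and `edges`.
#' @export
bud_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$from == edges$to)) stop("self-loop in edge list")
  if (any(!is.finite(edges$weight)) ||
      any(edges$weight <= 0) || any(edges$weight > 1))
    stop("edge weights must lie in (0, 1]")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicate undirected edge")
  endpoints <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- sort(endpoints)
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node id")
    if (!all(endpoints %in% nodes))
      stop("edge endpoint missing from node list")
  }
  structure(list(nodes = nodes,
                 edges = edges[, c("from", "to", "weight")]),
            class = "bud_network")
}

#' @export
print.bud_network <- function(x, ...) {
  cat(sprintf("bud_network: %d nodes, %d edges, weights in [%.3g, %.3g]\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) min(x$edges$weight) else NA,
              if (nrow(x$edges)) max(x$edges$weight) else NA))
  invisible(x)
}

#' Gene-set (pathway) collection
#'
#' @param sets named list of character vectors (unique member genes per set).
#' @param description optional character vector, one per set.
#' @return Object of class `bud_pathways`: list with `sets`, `description`.
#' @export
bud_pathways <- function(sets, description = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("set names must be present and unique")
    if (any(lengths(sets) == 0L)) stop("empty gene set")
    sets <- lapply(sets, function(g) unique(as.character(g)))
  }
  if (is.null(description)) description <- rep("", length(sets))
  if (length(description) != length(sets))
    stop("description length must match number of sets")
  names(description) <- names(sets)
  structure(list(sets = sets, description = description),
            class = "bud_pathways")
}

#' @export
print.bud_pathways <- function(x, ...) {
  cat(sprintf("bud_pathways: %d sets, sizes %s\n", length(x$sets),
              if (length(x$sets))
                paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
length.bud_pathways <- function(x) length(x$sets)

#' Normalized expression matrix
#'
#' @param values numeric matrix of normalized counts (genes x samples).
#' @param size_factors positive per-sample scaling factors.
#' @return Object of class `bud_norm`.
#' @export
bud_norm <- function(values, size_factors) {
  stopifnot(is.matrix(values), length(size_factors) == ncol(values))
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (any(values < 0)) stop("normalized values must be nonnegative")
  sf <- as.numeric(size_factors)
  names(sf) <- colnames(values)
  structure(list(values = values, size_factors = sf), class = "bud_norm")
}

#' @export
print.bud_norm <- function(x, ...) {
  cat(sprintf("bud_norm: %d genes x %d samples, size factors %.3g-%.3g\n",
              nrow(x$values), ncol(x$values),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}
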