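split_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds probe or gene
#' ids, and an optional second column (header one of `gene`, `symbol`,
#' `gene_symbol`, case-insensitive) holds gene symbols. All remaining cells
#' must be nonnegative integers.
#'
#' @param path TSV file path.
#' @param level `"probe"` or `"gene"`. Probe-level input requires the
#'   symbol column.
#' @return A [bud_counts] object.
#' @export
read_counts <- function(path, level = c("gene", "probe")) {
  level <- match.arg(level)
  fields <- split_tsv_lines(path)
  if (length(fields) < 2L) stop("count matrix needs a header and >= 1 row")
  widths <- lengths(fields)
  if (any(widths != widths[1L]))
    stop("ragged row at line ", which(widths != widths[1L])[1L])
  header <- fields[[1L]]
  has_sym <- length(header) >= 2L &&
    tolower(header[2L]) %in% c("gene", "symbol", "gene_symbol", "genesymbol")
  first_data <- 2L + has_sym
  if (length(header) < first_data)
    stop("no sample columns found")
  sample_ids <- header[first_data:length(header)]
  body <- fields[-1L]
  row_ids <- vapply(body, `[`, character(1L), 1L)
  symbols <- if (has_sym) vapply(body, `[`, character(1L), 2L) else NULL
  vals <- lapply(body, function(f) f[first_data:length(f)])
  num <- suppressWarnings(matrix(as.numeric(unlist(vals)),
                                 nrow = length(body), byrow = TRUE))
  if (any(is.na(num))) {
    bad <- which(rowSums(is.na(num)) > 0)[1L]
    stop("malformed count at line ", bad + 1L)
  }
  if (any(num < 0)) stop("negative count")
  if (any(num != round(num))) stop("non-integer count")
  storage.mode(num) <- "integer"
  rownames(num) <- row_ids
  colnames(num) <- sample_ids
  bud_counts(num, gene_symbols = symbols, level = level)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id` and `tb_level` (tokens low / intermediate /
#' high, case-insensitive). The binary class label is derived as 1 for high,
#' 0 for low, NA for intermediate.
#'
#' @param path TSV file path.
#' @return A [bud_samples] data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "tb_level") %in% names(df)))
    stop("sample sheet needs columns sample_id and tb_level")
  bud_samples(df$sample_id, df$tb_level)
}

#' Read a STRING-style edge list
#'
#' TSV with columns `protein1`, `protein2`, `combined_score`. Scores may be
#' on STRING's published 0-999 integer scale or already on the 0-1 scale;
#' the scale is auto-detected (any score > 1 implies the 0-999 scale and all
#' scores are divided by 1000), so re-reading a written 0-1 file never
#' rescales. Edges with weight strictly greater than `min_score` are kept;
#' duplicated undirected pairs are merged keeping the maximum weight and
#' self-loops are dropped.
#'
#' @param path TSV file path.
#' @param min_score confidence threshold on the 0-1 scale (default 0.4).
#' @return A [bud_network].
#' @export
read_string_edges <- function(path, min_score = 0.4) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    stop("edge list needs columns protein1, protein2, combined_score")
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(score)))
    stop("malformed score at line ", which(is.na(score))[1L] + 1L)
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0) || any(score > 1))
    stop("combined_score out of range after rescaling")
  a <- as.character(df$protein1)
  b <- as.character(df$protein2)
  keep <- a != b & score > min_score
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -score)
  first <- !duplicated(key[ord])
  idx <- ord[first]
  bud_network(data.frame(from = lo[idx], to = hi[idx], weight = score[idx],
                         stringsAsFactors = FALSE))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate genes within a line are collapsed; set sizes count unique genes.
#'
#' @param path GMT file path.
#' @return A [bud_pathways] collection (empty file gives an empty one).
#' @export
read_gmt <- function(path) {
  fields <- split_tsv_lines(path)
  if (!length(fields)) return(bud_pathways(list()))
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name: ", nm[duplicated(nm)][1L])
  desc <- vapply(fields, `[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  bud_pathways(sets, desc)
}

#' Write a result table as TSV
#'
#' Writes any of the pipeline's result data.frames (differential expression,
#' MI scores, diffusion scores, enrichment, ...) with full floating-point
#' precision so that [read_table()] round-trips losslessly.
#'
#' @param x a data.frame (or matrix, coerced with row names kept as a
#'   `row_id` column).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(row_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  df <- x
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV result table
#'
#' @param path TSV written by [write_table()].
#' @return data.frame with inferred column types.
#' @export
read_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
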