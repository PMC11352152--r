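# Quantitative evaluation of a gene panel's ability to separate the tumor-
# budding classes: sample-sample correlation structure, PCA onto the first
# two components, and a silhouette-based separation score. Expression is
# log2(x + 1)-transformed throughout.

panel_matrix <- function(norm, panel) {
  stopifnot(inherits(norm, "bud_norm"))
  panel <- unique(as.character(panel))
  missing <- setdiff(panel, rownames(norm$values))
  if (length(missing))
    stop("panel gene(s) absent from the matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  if (length(panel) < 2L) stop("panel must contain at least 2 genes")
  log2(norm$values[panel, , drop = FALSE] + 1)
}

#' Sample-sample correlation on a gene panel
#'
#' Pearson correlation between sample expression profiles restricted to the
#' panel, on the log2(x + 1) scale.
#'
#' @param norm [bud_norm].
#' @param panel character vector of >= 2 genes.
#' @return symmetric samples x samples correlation matrix.
#' @export
sample_correlation <- function(norm, panel) {
  x <- panel_matrix(norm, panel)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop("constant expression profile for sample ",
         colnames(x)[which(sds == 0)[1L]])
  cor(x)
}

#' PCA projection of samples on a gene panel
#'
#' Projects the standardized (per-gene centered and unit-variance)
#' log2(x + 1) sample profiles onto the first two principal components.
#' Genes with zero variance are dropped with a warning; if the data have
#' rank < 2 the second component is zeroed with a warning. The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive, making repeated runs identical.
#'
#' @param norm [bud_norm].
#' @param panel character vector of >= 2 genes.
#' @return list with `coords` (samples x 2), `var_explained` (fractions for
#'   PC1 and PC2) and `loadings`.
#' @export
pca_project <- function(norm, panel) {
  x <- panel_matrix(norm, panel)
  if (ncol(x) < 3L) stop("PCA needs at least 3 samples")
  m <- t(x)                              # samples x genes
  v <- apply(m, 2L, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) dropped from PCA")
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("fewer than 2 variable genes in panel")
  m <- scale(m)
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank2 <- min(2L, ncol(pc$rotation))
  coords <- matrix(0, nrow(m), 2L,
                   dimnames = list(rownames(m), c("PC1", "PC2")))
  load <- matrix(0, ncol(m), 2L,
                 dimnames = list(colnames(m), c("PC1", "PC2")))
  for (d in seq_len(rank2)) {
    rot <- pc$rotation[, d]
    if (rot[which.max(abs(rot))] < 0) rot <- -rot
    load[, d] <- rot
    coords[, d] <- m %*% rot
  }
  if (rank2 < 2L || ev[2L] < 1e-12 * ev[1L])
    warning("data rank < 2; second component is degenerate")
  list(coords = coords,
       var_explained = c(PC1 = ev[1L] / sum(ev),
                         PC2 = if (length(ev) > 1L) ev[2L] / sum(ev) else 0),
       loadings = load)
}

#' Silhouette-based class-separation score
#'
#' Mean silhouette coefficient of the samples under the binary class
#' labeling, with Euclidean distances either on supplied coordinates or on
#' the panel-restricted log2(x + 1) expression. For a singleton class the
#' within-class distance is taken as 0 (nearest-other-cluster only) and the
#' result carries attribute `flagged = TRUE`.
#'
#' @param x numeric matrix of sample coordinates (samples x features), e.g.
#'   PCA coordinates or `t(log2(values + 1))`.
#' @param class_labels vector with >= 2 distinct values, one per row of `x`.
#' @return mean silhouette in \[-1, 1\]; attribute `samples` holds the
#'   per-sample values.
#' @export
separation_score <- function(x, class_labels) {
  stopifnot(is.matrix(x), nrow(x) == length(class_labels))
  cl <- as.character(class_labels)
  if (length(unique(cl)) < 2L) stop("need at least two classes")
  d <- as.matrix(dist(x))
  s <- numeric(nrow(x))
  flagged <- FALSE
  for (i in seq_len(nrow(x))) {
    own <- which(cl == cl[i])
    other_classes <- setdiff(unique(cl), cl[i])
    b <- min(vapply(other_classes,
                    function(oc) mean(d[i, cl == oc]), numeric(1L)))
    if (length(own) == 1L) {
      a <- 0
      flagged <- TRUE
    } else {
      a <- mean(d[i, setdiff(own, i)])
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  out <- mean(s)
  attr(out, "samples") <- stats::setNames(s, rownames(x))
  attr(out, "flagged") <- flagged
  out
}

#' Evaluate a gene panel
#'
#' Bundles the correlation matrix, the 2-component PCA and the silhouette
#' separation score for a selected panel, restricted to class-labeled
#' samples.
#'
#' @param norm [bud_norm].
#' @param samples [bud_samples].
#' @param panel character vector of >= 2 genes.
#' @return list of class `bud_panel_eval` with `panel`, `correlation`,
#'   `pca`, `separation_score`.
#' @export
evaluate_panel <- function(norm, samples, panel) {
  stopifnot(inherits(samples, "bud_samples"))
  lab <- samples[!is.na(samples$class_label), , drop = FALSE]
  if (!all(lab$sample_id %in% colnames(norm$values)))
    stop("sample sheet contains samples absent from the matrix")
  sub <- bud_norm(norm$values[, lab$sample_id, drop = FALSE],
                  norm$size_factors[lab$sample_id])
  corr <- sample_correlation(sub, panel)
  pca <- pca_project(sub, panel)
  sep <- separation_score(t(panel_matrix(sub, panel)), lab$class_label)
  structure(list(panel = panel, correlation = corr, pca = pca,
                 separation_score = sep),
            class = "bud_panel_eval")
}

#' @export
print.bud_panel_eval <- function(x, ...) {
  cat(sprintf(paste0("bud_panel_eval: %d genes, separation score %.3f, ",
                     "PC1 %.1f%% / PC2 %.1f%% variance\n"),
              length(x$panel), as.numeric(x$separation_score),
              100 * x$pca$var_explained[1L], 100 * x$pca$var_explained[2L]))
  invisible(x)
}
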