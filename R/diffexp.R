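# Two-group negative-binomial Wald test, deliberately minimal: gene-wise
# method-of-moments dispersion, per-group log-mean fit by Newton scoring at
# fixed dispersion, Wald statistic on the log2 fold change. Variance model
# is NB2: Var = mu + alpha * mu^2.

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

#' Gene-wise dispersion by method of moments
#'
#' On the normalized scale, each class contributes a moment estimate
#' (s^2 - mean) / mean^2 of the NB2 dispersion; estimates are pooled across
#' classes with degrees-of-freedom weights and clipped at zero. Classes with
#' a single sample carry no variance information and are skipped with a
#' warning. Mode `"trend"` replaces the gene-wise estimates with a fitted
#' mean-dispersion trend alpha(mu) = a / mu + b.
#'
#' @param counts integer matrix (genes x samples) or a single gene row.
#' @param sf positive per-sample size factors.
#' @param class binary vector (0/1), one value per sample.
#' @param mode `"gene"` (default) or `"trend"`.
#' @param floor lower bound applied to the returned dispersions
#'   (default 1e-8; set 0 for the raw clipped-at-zero estimate).
#' @return numeric vector of dispersions; NA for all-zero genes, which are
#'   excluded from testing downstream.
#' @export
estimate_dispersion <- function(counts, sf, class, mode = c("gene", "trend"),
                                floor = 1e-8) {
  mode <- match.arg(mode)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(length(sf) == ncol(counts), length(class) == ncol(counts))
  class <- as.integer(class)
  if (!all(class %in% 0:1)) stop("class must be binary 0/1")
  x <- sweep(counts, 2L, sf, "/")
  num <- rep(0, nrow(counts))
  den <- rep(0, nrow(counts))
  for (cl in 0:1) {
    idx <- which(class == cl)
    if (length(idx) == 0L) stop("both classes must be present")
    if (length(idx) < 2L) {
      warning("class ", cl, " has a single sample; it contributes no ",
              "dispersion information")
      next
    }
    xc <- x[, idx, drop = FALSE]
    mu <- rowMeans(xc)
    v <- row_vars(xc)
    w <- length(idx) - 1L
    contrib <- ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
    use <- !is.na(contrib)
    num[use] <- num[use] + w * contrib[use]
    den[use] <- den[use] + w
  }
  alpha <- ifelse(den > 0, pmax(0, num / den), NA_real_)
  all_zero <- rowSums(counts) == 0
  alpha[all_zero] <- NA_real_
  if (mode == "trend") {
    mu_all <- rowMeans(x)
    ok <- !is.na(alpha) & mu_all > 0
    if (sum(ok) >= 10L) {
      fit <- lm(alpha[ok] ~ I(1 / mu_all[ok]))
      pred <- coef(fit)[1L] + coef(fit)[2L] / mu_all
      alpha[ok] <- pmax(0, pred[ok])
    } else {
      warning("too few genes to fit a dispersion trend; keeping gene-wise")
    }
  }
  out <- pmax(alpha, floor)
  out[is.na(alpha)] <- NA_real_
  out
}

# Newton scoring for the per-group log mean b (mu_j = sf_j * exp(b)) of an
# NB2 model at fixed dispersion, vectorized across genes. Returns the
# estimate and the expected information sum(mu / (1 + alpha*mu)).
nb_group_fit <- function(counts, sf, alpha, pseudo_mean) {
  tot <- rowSums(counts)
  zero <- tot == 0
  b <- log(ifelse(zero, pseudo_mean, tot / sum(sf)))
  active <- which(!zero)
  for (iter in seq_len(100L)) {
    if (!length(active)) break
    mu <- exp(b[active]) %o% sf
    den <- 1 + alpha[active] * mu
    U <- rowSums((counts[active, , drop = FALSE] - mu) / den)
    J <- rowSums(mu / den)
    step <- U / J
    step <- pmin(pmax(step, -5), 5)
    b[active] <- b[active] + step
    active <- active[abs(step) > 1e-12]
  }
  mu <- exp(b) %o% sf
  J <- rowSums(mu / (1 + alpha * mu))
  list(b = b, info = J, zero = zero)
}

#' Negative-binomial Wald differential-expression test
#'
#' Fits a two-group NB generalized linear model with log link and sample
#' size-factor offsets at fixed gene-wise dispersion, and tests the log2
#' fold change (high / low) with a Wald statistic against the standard
#' normal. Genes with zero counts everywhere are flagged and excluded from
#' testing (they do not count toward the Benjamini-Hochberg denominator);
#' a class that is entirely zero for a gene is replaced by the pseudo-mean
#' 0.5 / mean(size factors) and the row is flagged.
#'
#' @param m gene-level [bud_counts].
#' @param samples [bud_samples]; only samples with a binary class label are
#'   used.
#' @param dispersion optional numeric vector of fixed dispersions (one per
#'   gene); default is [estimate_dispersion()].
#' @param dispersion_mode passed to [estimate_dispersion()].
#' @return data.frame with columns `gene`, `baseMean`, `logFC`, `lfcSE`,
#'   `stat`, `pvalue`, `padj`, `flag` (`""`, `"zero_high"`, `"zero_low"` or
#'   `"untested"`). `baseMean` is the mean normalized count over the used
#'   samples; `stat = logFC / lfcSE`.
#' @export
run_diffexp <- function(m, samples, dispersion = NULL,
                        dispersion_mode = c("gene", "trend")) {
  stopifnot(inherits(m, "bud_counts"), inherits(samples, "bud_samples"))
  if (m$level != "gene") stop("run_diffexp expects gene-level counts")
  lab <- samples[!is.na(samples$class_label), , drop = FALSE]
  if (!all(lab$sample_id %in% colnames(m$counts)))
    stop("sample sheet contains samples absent from the count matrix")
  if (!any(lab$class_label == 1L) || !any(lab$class_label == 0L))
    stop("both a high- and a low-TB class are required")
  counts <- m$counts[, lab$sample_id, drop = FALSE]
  cls <- lab$class_label
  sub <- bud_counts(counts, gene_symbols = m$gene_symbols, level = "gene")
  sf <- size_factors(sub)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, sf, cls,
                                      mode = match.arg(dispersion_mode))
  stopifnot(length(dispersion) == nrow(counts))
  norm <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  pseudo <- 0.5 / mean(sf)
  alpha_fit <- ifelse(is.na(dispersion), 0, dispersion)
  hi <- nb_group_fit(counts[, cls == 1L, drop = FALSE], sf[cls == 1L],
                     alpha_fit, pseudo)
  lo <- nb_group_fit(counts[, cls == 0L, drop = FALSE], sf[cls == 0L],
                     alpha_fit, pseudo)
  log2fc <- (hi$b - lo$b) / log(2)
  se <- sqrt(1 / hi$info + 1 / lo$info) / log(2)
  stat <- log2fc / se
  pval <- 2 * pnorm(-abs(stat))
  tested <- !is.na(dispersion)
  flag <- rep("", nrow(counts))
  flag[hi$zero] <- "zero_high"
  flag[lo$zero] <- "zero_low"
  flag[!tested] <- "untested"
  pval[!tested] <- NA_real_
  stat[!tested] <- NA_real_
  padj <- rep(NA_real_, length(pval))
  padj[tested] <- adjust_bh(pval[tested])
  data.frame(gene = rownames(counts), baseMean = base_mean,
             logFC = ifelse(tested, log2fc, NA_real_),
             lfcSE = ifelse(tested, se, NA_real_),
             stat = stat, pvalue = pval, padj = padj, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; the denominator m is the number
#' of p-values supplied, so callers must exclude untested genes first.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Filter differentially expressed genes
#'
#' Keeps genes with adjusted p-value strictly below `alpha` and absolute
#' log2 fold change strictly above `min_abs_lfc`.
#'
#' @param tab result of [run_diffexp()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_abs_lfc |log2 FC| threshold (default 1.5).
#' @return character vector of gene names, in table order.
#' @export
filter_degs <- function(tab, alpha = 0.05, min_abs_lfc = 1.5) {
  stopifnot(all(c("gene", "padj", "logFC") %in% names(tab)))
  keep <- !is.na(tab$padj) & tab$padj < alpha & abs(tab$logFC) > min_abs_lfc
  tab$gene[keep]
}
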