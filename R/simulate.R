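# Synthetic-data generators reproducing the statistical structure the
# pipeline assumes: negative-binomial counts over a small imbalanced
# two-class design (default 12 high-TB vs 3 low-TB samples), a planted set
# of differentially expressed genes, a planted set of perfect class
# separators (non-overlapping expression ranges, so they attain the maximal
# mutual information H(Y)), scale-free or block-model interaction networks
# with confidence weights above the STRING reading threshold, and pathway
# collections enriched around planted seed genes. All randomness flows from
# one explicit integer seed; the global RNG state is left untouched.

#' Simulate a two-class count matrix with planted structure
#'
#' Counts are drawn as `count ~ NB(mean = s_j * q_gc, dispersion)` with
#' per-sample size factors `s_j` log-uniform over `depth_range` and NB2
#' variance `mu + dispersion * mu^2` (`dispersion = 0` gives Poisson). A
#' fraction `de_fraction` of genes get a symmetric log2 effect drawn around
#' `lfc_location` with random sign. `n_separators` of the planted
#' up-regulated genes are made perfect class separators: zero counts in the
#' low class and counts tightly clustered around a high target in the high
#' class, so their expression ranges never overlap between classes.
#'
#' @param n_genes number of genes.
#' @param n_high,n_low class sizes (defaults 12 and 3, the motivating
#'   cohort). `n_low = 1` is allowed with a warning.
#' @param de_fraction fraction of genes with a planted effect, in \[0, 1\].
#' @param lfc_location center of the |log2 fold change| distribution
#'   (log2 units).
#' @param dispersion NB2 dispersion shared across genes, or
#'   `per_gene_dispersion = TRUE` to draw gene-wise dispersions from a
#'   Gamma distribution with this mean.
#' @param depth_range positive pair; size factors are log-uniform over it.
#' @param n_separators number of planted perfect separators (default 7).
#' @param rng_seed integer seed.
#' @param per_gene_dispersion draw per-gene Gamma dispersions (default
#'   FALSE: single shared value).
#' @return list with `counts` ([bud_counts], gene level), `samples`
#'   ([bud_samples]) and `truth` (list: `de_genes` data.frame with
#'   `gene`/`true_lfc`, `separator_genes`, `seed_genes`, `enriched_sets`,
#'   `rng_seed`).
#' @export
simulate_counts <- function(n_genes = 2000, n_high = 12, n_low = 3,
                            de_fraction = 0.05, lfc_location = 2.5,
                            dispersion = 0.1, depth_range = c(0.5, 2),
                            n_separators = 7, rng_seed = 1,
                            per_gene_dispersion = FALSE) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (n_high < 2) stop("n_high must be >= 2")
  if (n_low < 1) stop("n_low must be >= 1")
  if (n_low < 2) warning("n_low = 1: dispersion is informed by one class only")
  stopifnot(length(depth_range) == 2L, all(depth_range > 0),
            depth_range[1] <= depth_range[2], dispersion >= 0)
  n_de <- round(de_fraction * n_genes)
  if (n_separators > max(n_de, 0))
    stop("n_separators cannot exceed the number of planted DE genes")
  n <- n_high + n_low
  withr::with_seed(rng_seed, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    sample_ids <- sprintf("S%02d", seq_len(n))
    tb <- c(rep("high", n_high), rep("low", n_low))
    sf <- exp(runif(n, log(depth_range[1]), log(depth_range[2])))
    q <- exp(rnorm(n_genes, log(100), 1.3))
    alpha <- if (per_gene_dispersion && dispersion > 0)
      stats::rgamma(n_genes, shape = 4, rate = 4 / dispersion)
    else rep(dispersion, n_genes)
    de_idx <- sample.int(n_genes, n_de)
    sep_idx <- if (n_separators > 0) de_idx[seq_len(n_separators)] else integer()
    lfc <- rep(0, n_genes)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      rnorm(n_de, lfc_location, 0.25)
    q_high <- q * 2^(lfc / 2)
    q_low <- q * 2^(-lfc / 2)
    draw <- function(mu_vec, a_vec) {
      if (all(a_vec == 0)) stats::rpois(length(mu_vec), mu_vec)
      else rnbinom(length(mu_vec), mu = mu_vec,
                   size = ifelse(a_vec > 0, 1 / a_vec, Inf))
    }
    counts <- matrix(0L, n_genes, n, dimnames = list(genes, sample_ids))
    for (j in seq_len(n)) {
      mu <- if (tb[j] == "high") q_high else q_low
      counts[, j] <- as.integer(draw(sf[j] * mu, alpha))
    }
    # separators: zero in one class, tightly clustered positive values in
    # the other, so the normalized ranges cannot overlap under any monotone
    # binning; directions alternate (like real biomarker panels mixing up-
    # and down-regulated genes), which keeps per-sample panel profiles
    # non-constant within a class
    if (length(sep_idx)) {
      mu_sep <- runif(length(sep_idx), 100, 400)
      for (s in seq_along(sep_idx)) {
        g <- sep_idx[s]
        up <- s %% 2L == 1L
        zero_class <- if (up) "low" else "high"
        expr_class <- if (up) "high" else "low"
        counts[g, tb == zero_class] <- 0L
        counts[g, tb == expr_class] <-
          as.integer(round(mu_sep[s] * sf[tb == expr_class]))
        lfc[g] <- if (up) Inf else -Inf
      }
    }
    truth <- list(
      de_genes = data.frame(gene = genes[de_idx],
                            true_lfc = lfc[de_idx],
                            stringsAsFactors = FALSE),
      separator_genes = genes[sep_idx],
      seed_genes = genes[sep_idx],
      enriched_sets = character(),
      rng_seed = rng_seed
    )
    list(counts = bud_counts(counts, level = "gene"),
         samples = bud_samples(sample_ids, tb),
         truth = truth)
  })
}

# Barabasi-Albert growth with m isolated initial nodes: the first attached
# node links to all of them, later nodes pick m distinct targets by
# preferential attachment, giving exactly m * (n - m) edges and a connected
# graph.
ba_edges <- function(n, m) {
  stopifnot(n > m, m >= 1)
  from <- integer(0); to <- integer(0)
  repeated <- integer(0)
  targets <- seq_len(m)
  for (v in (m + 1L):n) {
    from <- c(from, rep(v, m)); to <- c(to, targets)
    repeated <- c(repeated, targets, rep(v, m))
    targets <- unique(sample(repeated))[seq_len(m)]
  }
  data.frame(from = from, to = to)
}

#' Simulate a protein-protein interaction network
#'
#' Generates a connected undirected graph under a Barabasi-Albert
#' preferential-attachment model (scale-free, like PPI degree
#' distributions) or a stochastic block model (planted communities), and
#' assigns confidence weights uniform in (0.4, 1.0] so that every edge
#' survives the STRING reading threshold.
#'
#' @param n_nodes number of nodes (>= 10).
#' @param model `"barabasi_albert"` (params: `m`, attachments per node,
#'   default 3) or `"stochastic_block"` (params: `n_blocks` default 4,
#'   `p_within` default 0.15, `p_between` default 0.01).
#' @param params list of model parameters.
#' @param rng_seed integer seed.
#' @param node_names optional character vector of node labels (length
#'   `n_nodes`); default `N0001`, ... Under `stochastic_block` a
#'   disconnected draw is reduced to its largest component with a warning.
#' @return A [bud_network]. For the block model, attribute `block` records
#'   each node's community.
#' @export
simulate_network <- function(n_nodes, model = c("barabasi_albert",
                                                "stochastic_block"),
                             params = list(), rng_seed = 1,
                             node_names = NULL) {
  model <- match.arg(model)
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  if (is.null(node_names)) node_names <- sprintf("N%04d", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))
  withr::with_seed(rng_seed, {
    block <- NULL
    if (model == "barabasi_albert") {
      m <- if (is.null(params$m)) 3L else as.integer(params$m)
      ed <- ba_edges(n_nodes, m)
      keep_nodes <- seq_len(n_nodes)
    } else {
      n_blocks <- if (is.null(params$n_blocks)) 4L else as.integer(params$n_blocks)
      p_within <- if (is.null(params$p_within)) 0.15 else params$p_within
      p_between <- if (is.null(params$p_between)) 0.01 else params$p_between
      sizes <- rep(n_nodes %/% n_blocks, n_blocks)
      sizes[1L] <- sizes[1L] + n_nodes %% n_blocks
      pm <- matrix(p_between, n_blocks, n_blocks)
      diag(pm) <- p_within
      g <- igraph::sample_sbm(n_nodes, pref.matrix = pm, block.sizes = sizes)
      comp <- igraph::components(g)
      keep_nodes <- seq_len(n_nodes)
      if (comp$no > 1L) {
        warning("stochastic block draw disconnected; keeping largest ",
                "component (", max(comp$csize), " of ", n_nodes, " nodes)")
        keep <- which(comp$membership == which.max(comp$csize))
        g <- igraph::induced_subgraph(g, keep)
        keep_nodes <- keep
      }
      ed <- as.data.frame(igraph::as_edgelist(g, names = FALSE))
      names(ed) <- c("from", "to")
      block <- rep(seq_len(n_blocks), sizes)[keep_nodes]
    }
    nm <- node_names[keep_nodes]
    w <- 0.4 + runif(nrow(ed)) * 0.6
    net <- bud_network(
      data.frame(from = nm[ed$from], to = nm[ed$to], weight = w,
                 stringsAsFactors = FALSE),
      nodes = nm)
    if (!is.null(block)) attr(net, "block") <- stats::setNames(block, nm)
    net
  })
}

#' Simulate a pathway collection with planted enrichment
#'
#' Builds `n_enriched` gene sets predominantly (>= 70% of members) from the
#' two-hop graph neighborhood of the planted seed genes, plus uniformly
#' random sets, with sizes drawn within `size_range`.
#'
#' @param network [bud_network].
#' @param seed_genes character vector, subset of the network nodes.
#' @param n_sets total number of sets.
#' @param size_range integer pair within the node count.
#' @param n_enriched number of neighborhood-enriched sets.
#' @param rng_seed integer seed.
#' @return A [bud_pathways]; attribute `enriched_sets` names the planted
#'   ones.
#' @export
simulate_pathways <- function(network, seed_genes, n_sets = 50,
                              size_range = c(10, 40), n_enriched = 3,
                              rng_seed = 1) {
  stopifnot(inherits(network, "bud_network"), n_enriched <= n_sets)
  if (!all(seed_genes %in% network$nodes))
    stop("seed_genes must all be network nodes")
  n_nodes <- length(network$nodes)
  if (size_range[2] > n_nodes)
    stop("size_range exceeds the node count")
  if (size_range[1] < 1 || size_range[1] > size_range[2])
    stop("invalid size_range")
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  hop1 <- setdiff(unique(names(unlist(
    igraph::ego(g, order = 1, nodes = seed_genes)))), seed_genes)
  hop2 <- setdiff(unique(names(unlist(
    igraph::ego(g, order = 2, nodes = seed_genes)))),
    c(seed_genes, hop1))
  withr::with_seed(rng_seed, {
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    enriched <- if (n_enriched > 0) names(sets)[seq_len(n_enriched)]
                else character()
    for (i in seq_len(n_sets)) {
      size <- sample(seq(size_range[1], size_range[2]), 1L)
      if (i <= n_enriched) {
        # fill the neighborhood quota from the seeds outward, so the set
        # concentrates where diffusion mass actually lands
        k_nb <- min(ceiling(0.7 * size),
                    length(seed_genes) + length(hop1) + length(hop2))
        inside <- head(c(sample(seed_genes), sample(hop1), sample(hop2)),
                       k_nb)
        outside <- sample(setdiff(network$nodes, inside), size - k_nb)
        sets[[i]] <- c(inside, outside)
      } else {
        sets[[i]] <- sample(network$nodes, size)
      }
    }
    db <- bud_pathways(sets, rep("synthetic", n_sets))
    attr(db, "enriched_sets") <- enriched
    db
  })
}
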