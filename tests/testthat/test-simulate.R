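test_that("count simulation records its planted truth", {
  sim <- simulate_counts(n_genes = 2000, n_high = 12, n_low = 3,
                         de_fraction = 0.05, rng_seed = 7)
  expect_equal(dim(sim$counts), c(2000L, 15L))
  expect_equal(nrow(sim$truth$de_genes), 100L)
  expect_equal(sum(sim$samples$class_label == 1L), 12L)
  expect_equal(sum(sim$samples$class_label == 0L), 3L)
  expect_true(all(sim$truth$separator_genes %in% sim$truth$de_genes$gene))
  expect_true(all(sim$truth$de_genes$gene %in% sim$counts$gene_symbols))

  # determinism under a fixed seed, and no global RNG disturbance
  before <- withr::with_seed(1, runif(1))
  sim2 <- simulate_counts(n_genes = 2000, rng_seed = 7)
  expect_identical(sim$counts$counts, sim2$counts$counts)

  expect_error(simulate_counts(de_fraction = 1.2), "de_fraction")
  expect_error(simulate_counts(n_high = 1), "n_high")
  expect_warning(simulate_counts(n_genes = 50, n_low = 1, n_separators = 2,
                                 rng_seed = 3), "one class")
})

test_that("zero dispersion approaches the Poisson variance-mean ratio", {
  sim <- simulate_counts(n_genes = 1500, n_high = 30, n_low = 30,
                         de_fraction = 0, n_separators = 0, dispersion = 0,
                         depth_range = c(1, 1), rng_seed = 19)
  x <- sim$counts$counts
  ratio <- apply(x, 1, var) / pmax(rowMeans(x), 1e-9)
  expect_equal(median(ratio), 1, tolerance = 0.1)
})

test_that("planted separators attain the MI ceiling and top every gene", {
  sim <- simulate_counts(n_genes = 500, rng_seed = 23)
  norm <- normalize_counts(sim$counts)
  tab <- mi_table(norm, sim$samples)
  hy <- entropy(sim$samples$class_label)
  seps <- sim$truth$separator_genes
  expect_equal(tab$mi_score[match(seps, tab$gene)], rep(hy, length(seps)),
               tolerance = 1e-12)
  expect_true(all(seps %in% select_top_mi(tab)))
  expect_lte(max(tab$mi_score), hy + 1e-9)
})

test_that("scale-free networks have the closed-form edge count and valid weights", {
  net <- simulate_network(500, model = "barabasi_albert",
                          params = list(m = 3), rng_seed = 1)
  expect_length(net$nodes, 500)
  expect_equal(nrow(net$edges), 3 * (500 - 3))
  expect_true(all(net$edges$weight > 0.4 & net$edges$weight <= 1))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  expect_equal(igraph::components(g)$no, 1L)

  net2 <- simulate_network(500, params = list(m = 3), rng_seed = 1)
  expect_identical(net$edges, net2$edges)
  expect_error(simulate_network(5), ">= 10")
})

test_that("sparse block models fall back to their largest component", {
  expect_warning(net <- simulate_network(
    60, model = "stochastic_block",
    params = list(n_blocks = 3, p_within = 0.3, p_between = 0),
    rng_seed = 5), "largest component")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  expect_equal(igraph::components(g)$no, 1L)
})

test_that("pathway simulation respects sizes, seeds and determinism", {
  net <- simulate_network(200, rng_seed = 2)
  seeds <- net$nodes[1:5]
  db <- simulate_pathways(net, seeds, n_sets = 50, size_range = c(10, 40),
                          n_enriched = 3, rng_seed = 9)
  expect_length(db, 50)
  expect_true(all(lengths(db$sets) >= 10 & lengths(db$sets) <= 40))
  expect_length(attr(db, "enriched_sets"), 3)
  db2 <- simulate_pathways(net, seeds, n_sets = 50, size_range = c(10, 40),
                           n_enriched = 3, rng_seed = 9)
  expect_identical(db$sets, db2$sets)
  expect_error(simulate_pathways(net, seeds, size_range = c(10, 500)),
               "node count")
  expect_error(simulate_pathways(net, "not_a_node"), "network nodes")
})

test_that("with no planted enrichment the diffusion query stays null", {
  clean <- vapply(1:200, function(rep) {
    net <- simulate_network(150, rng_seed = 5000 + rep)
    seeds <- net$nodes[1:5]
    db <- simulate_pathways(net, seeds, n_sets = 30, size_range = c(10, 25),
                            n_enriched = 0, rng_seed = 6000 + rep)
    r <- diffuse(net, seeds, alpha = 1)
    cand <- percentile_cutoff(r)
    res <- enrich(union(cand, seeds), db, universe = net$nodes, alpha = 1 - 1e-12)
    !any(res$padj < 0.01)
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("the differential-expression stage recovers planted genes (single run)", {
  sim <- simulate_counts(n_genes = 2000, rng_seed = 31)
  tab <- run_diffexp(sim$counts, sim$samples)
  degs <- filter_degs(tab)
  truth <- sim$truth$de_genes$gene
  expect_gte(mean(truth %in% degs), 0.5)               # power
  expect_lte(mean(!(degs %in% truth)), 0.10)           # observed FDR
})
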