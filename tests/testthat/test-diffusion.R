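test_that("seed set is the sorted intersection with network matching", {
  net <- path3_network()
  seeds <- build_seed_set(c("n3", "n2", "A"), c("n2", "n3", "B"), net)
  expect_equal(seeds$genes, c("n2", "n3"))
  expect_equal(seeds$matched, c("n2", "n3"))
  expect_warning(s2 <- build_seed_set(c("n1", "X"), c("X", "n1"), net),
                 "absent from the network")
  expect_equal(s2$unmatched, "X")
  expect_error(build_seed_set("a", "b", net), "no seeds")
})

test_that("3-node path kernel matches the hand-inverted system", {
  net <- path3_network()
  sys <- build_kernel_system(net, alpha = 1)
  # the hand-inverted kernel is (1/8) [[5,2,1],[2,4,2],[1,2,5]]
  K <- solve(as.matrix(sys$A))
  expect_equal(unname(K), matrix(c(5, 2, 1, 2, 4, 2, 1, 2, 5), 3) / 8,
               tolerance = 1e-12)
  r <- diffuse(net, "n1", alpha = 1)
  expect_equal(r$score[match(c("n1", "n2", "n3"), r$node)],
               c(0.625, 0.25, 0.125), tolerance = 1e-10)

  # alpha = 0 returns the seed indicator
  r0 <- diffuse(net, "n1", alpha = 0)
  expect_equal(r0$score[match(c("n1", "n2", "n3"), r0$node)], c(1, 0, 0))
  expect_error(build_kernel_system(net, alpha = -0.5), "nonnegative")

  # the Laplacian annihilates constants: (I + aL) 1 = 1
  for (a in c(0.3, 1, 5)) {
    A <- build_kernel_system(net, alpha = a)$A
    expect_equal(as.numeric(A %*% rep(1, 3)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("diffusion conserves seed mass and stays nonnegative", {
  for (seed in 1:5) {
    net <- random_connected_network(80, 0.06, seed = seed)
    withr::with_seed(seed, {
      n_seed <- sample(1:6, 1)
      seeds <- sample(net$nodes, n_seed)
    })
    for (a in c(0.1, 1, 10)) {
      r <- diffuse(net, seeds, alpha = a)
      expect_equal(sum(r$score), n_seed, tolerance = 1e-6)
      expect_true(all(r$score >= 0))
    }
  }
})

test_that("sparse solve equals dense kernel inversion", {
  for (seed in c(2, 4)) {
    net <- random_connected_network(150, 0.04, seed = seed)
    seeds <- net$nodes[c(1, 10, 30)]
    a <- 0.8
    r <- diffuse(net, seeds, alpha = a)
    K <- solve(dense_system(net, a))
    y <- as.numeric(net$nodes %in% seeds)
    expect_equal(r$score[match(net$nodes, r$node)],
                 as.numeric(K %*% y), tolerance = 1e-8)
  }
})

test_that("symmetric seeds give symmetric scores; seedless components score 0", {
  # path n1-n2-n3 with seeds at both ends: symmetry swaps n1 and n3
  r <- diffuse(path3_network(), c("n1", "n3"), alpha = 2)
  expect_equal(r$score[r$node == "n1"], r$score[r$node == "n3"])

  # two disjoint components, seed in the first only
  net <- bud_network(data.frame(from = c("a1", "b1"), to = c("a2", "b2"),
                                weight = c(0.9, 0.9)))
  r2 <- diffuse(net, "a1", alpha = 1)
  expect_equal(r2$score[r2$node %in% c("b1", "b2")], c(0, 0))
  expect_equal(sum(r2$score), 1, tolerance = 1e-12)
})

test_that("scores flatten as alpha grows and concentrate near seed communities", {
  net <- random_connected_network(100, 0.06, seed = 8)
  seeds <- net$nodes[1:3]
  vars <- vapply(c(0.1, 1, 10, 100), function(a)
    var(diffuse(net, seeds, alpha = a)$score), numeric(1))
  expect_true(all(diff(vars) < 0))

  # planted-community locality: seeds inside one block score higher inside
  for (rep in 1:20) {
    net <- simulate_network(120, model = "stochastic_block",
                            params = list(n_blocks = 3, p_within = 0.25,
                                          p_between = 0.01),
                            rng_seed = 300 + rep)
    block <- attr(net, "block")
    inside <- names(block)[block == 1]
    seeds <- inside[1:3]
    for (a in c(0.1, 1, 10)) {
      r <- diffuse(net, seeds, alpha = a)
      m_in <- mean(r$score[r$node %in% setdiff(inside, seeds)])
      m_out <- mean(r$score[!(r$node %in% inside)])
      expect_gt(m_in, m_out)
    }
  }
})

test_that("percentile cutoff fills a ceiling quota of non-seed nodes", {
  fake <- function(n, n_seed = 0) {
    data.frame(node = sprintf("n%05d", seq_len(n)),
               score = seq(n, 1) / n,
               is_seed = c(rep(TRUE, n_seed), rep(FALSE, n - n_seed)))
  }
  expect_length(percentile_cutoff(fake(19038)), 191)
  expect_length(percentile_cutoff(fake(500)), 5)
  expect_length(percentile_cutoff(fake(100)), 1)
  # seeds do not consume the quota when excluded (default)
  r <- fake(100, n_seed = 2)
  expect_equal(percentile_cutoff(r), "n00003")
  expect_equal(percentile_cutoff(r, exclude_seeds = FALSE), "n00001")
  # boundary ties break by node id
  tie <- data.frame(node = c("b", "a", "c"), score = c(0.5, 0.5, 0.5),
                    is_seed = FALSE)
  expect_equal(percentile_cutoff(tie, percentile = 50), c("a", "b"))
  expect_warning(out <- percentile_cutoff(fake(100, n_seed = 99),
                                          percentile = 98), "quota")
  expect_length(out, 1)
  expect_error(percentile_cutoff(fake(10), percentile = 0), "strictly")
})
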