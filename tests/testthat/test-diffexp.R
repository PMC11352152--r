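make_two_group_counts <- function(n_genes, n_high, n_low, mu, dispersion,
                                  seed, lfc = rep(0, n_genes)) {
  withr::with_seed(seed, {
    n <- n_high + n_low
    sf <- exp(runif(n, log(0.7), log(1.4)))
    q_h <- mu * 2^(lfc / 2); q_l <- mu * 2^(-lfc / 2)
    counts <- sapply(seq_len(n), function(j) {
      q <- if (j <= n_high) q_h else q_l
      if (dispersion == 0) rpois(n_genes, sf[j] * q)
      else rnbinom(n_genes, mu = sf[j] * q, size = 1 / dispersion)
    })
    dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                             sprintf("S%02d", seq_len(n)))
    list(counts = counts, sf = sf,
         class = c(rep(1L, n_high), rep(0L, n_low)))
  })
}

test_that("moment dispersion estimates recover the truth", {
  # exact zero when the within-class variance equals the mean
  x <- rbind(g1 = c(0L, 1L, 2L, 0L, 1L, 2L))  # var 1 = mean 1 per class
  a <- estimate_dispersion(x, rep(1, 6), c(1, 1, 1, 0, 0, 0), floor = 0)
  expect_equal(a, 0)
  x2 <- rbind(g1 = c(0L, 2L, 4L, 0L, 2L, 4L))  # var 4 = 2 * mean
  a2 <- estimate_dispersion(x2, rep(1, 6), c(1, 1, 1, 0, 0, 0), floor = 0)
  expect_equal(a2, (4 - 2) / 4)

  # Poisson data: estimates shrink toward zero with growing n
  d <- make_two_group_counts(1000, 25, 25, mu = 100, dispersion = 0, seed = 1)
  a_pois <- estimate_dispersion(d$counts, d$sf, d$class, floor = 0)
  expect_lte(median(a_pois), 0.02)

  # NB alpha = 0.1 recovered within a factor of two at n = 50
  d2 <- make_two_group_counts(1000, 25, 25, mu = 100, dispersion = 0.1,
                              seed = 2)
  a_nb <- estimate_dispersion(d2$counts, d2$sf, d2$class, floor = 0)
  expect_gte(median(a_nb), 0.05)
  expect_lte(median(a_nb), 0.2)

  # all-zero genes are flagged as untestable
  z <- rbind(g1 = rep(0L, 6))
  expect_true(is.na(estimate_dispersion(z, rep(1, 6),
                                        c(1, 1, 1, 0, 0, 0))))
})

test_that("Wald table satisfies its internal consistency contracts", {
  d <- make_two_group_counts(300, 12, 3, mu = 80, dispersion = 0.1, seed = 5,
                             lfc = c(rep(2.5, 30), rep(0, 270)))
  m <- bud_counts(d$counts)
  ann <- cohort_samples()
  tab <- run_diffexp(m, ann)
  ok <- !is.na(tab$pvalue)
  expect_true(any(ok))
  expect_equal(tab$stat[ok], tab$logFC[ok] / tab$lfcSE[ok], tolerance = 1e-9)
  expect_equal(tab$pvalue[ok], 2 * pnorm(-abs(tab$stat[ok])))
  expect_true(all(tab$pvalue[ok] >= 0 & tab$pvalue[ok] <= 1))
  expect_true(all(tab$padj[ok] >= tab$pvalue[ok]))
  # padj nondecreasing in p-value rank
  o <- order(tab$pvalue[ok])
  expect_true(all(diff(tab$padj[ok][o]) >= -1e-12))
  # baseMean is the mean normalized count
  sf <- size_factors(m)
  expect_equal(tab$baseMean, unname(rowMeans(sweep(d$counts, 2, sf, "/"))))
})

test_that("identical group means give logFC 0 and p-value 1", {
  counts <- matrix(rep(c(10L, 20L, 30L), 5)[1:15], 1, 15,
                   dimnames = list("g1", sprintf("S%02d", 1:15)))
  counts <- rbind(g1 = rep(12L, 15), g2 = rep(c(5L, 9L), 8)[1:15])
  colnames(counts) <- sprintf("S%02d", 1:15)
  tab <- run_diffexp(bud_counts(counts[1, , drop = FALSE] ),
                     cohort_samples())
  expect_equal(tab$logFC[1], 0, tolerance = 1e-10)
  expect_equal(tab$pvalue[1], 1, tolerance = 1e-10)
})

test_that("a class with all-zero counts is replaced by the pseudo-mean and flagged", {
  counts <- rbind(g1 = c(rep(40L, 12), rep(0L, 3)),
                  g2 = rep(10L, 15))
  colnames(counts) <- sprintf("S%02d", 1:15)
  tab <- run_diffexp(bud_counts(counts), cohort_samples())
  expect_equal(tab$flag[1], "zero_low")
  expect_true(is.finite(tab$logFC[1]) && tab$logFC[1] > 0)
  all_zero <- rbind(g1 = rep(0L, 15), g2 = rep(10L, 15))
  colnames(all_zero) <- sprintf("S%02d", 1:15)
  tab2 <- run_diffexp(bud_counts(all_zero), cohort_samples())
  expect_equal(tab2$flag[1], "untested")
  expect_true(is.na(tab2$pvalue[1]))
})

test_that("at zero dispersion the fit agrees with a Poisson GLM", {
  d <- make_two_group_counts(50, 6, 4, mu = 60, dispersion = 0, seed = 9,
                             lfc = rnorm(50, 0, 1))
  m <- bud_counts(d$counts)
  ann <- bud_samples(colnames(d$counts),
                     ifelse(d$class == 1, "high", "low"))
  sf <- size_factors(m)
  tab <- run_diffexp(m, ann, dispersion = rep(0, 50))
  for (g in c(1, 7, 23, 50)) {
    fit <- glm(d$counts[g, ] ~ factor(d$class, levels = c(0, 1)) +
                 offset(log(sf)), family = poisson())
    expect_equal(tab$logFC[g], unname(coef(fit)[2]) / log(2),
                 tolerance = 1e-6)
  }
})

test_that("raising high-class counts never lowers the fold change", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      base <- rbind(g = rpois(15, 50))
      colnames(base) <- sprintf("S%02d", 1:15)
      up <- base
      up[1, 1:12] <- up[1, 1:12] + sample(0:20, 12, TRUE)
      disp <- rep(0.1, 1)
      t1 <- run_diffexp(bud_counts(base), cohort_samples(),
                        dispersion = disp)
      t2 <- run_diffexp(bud_counts(up), cohort_samples(), dispersion = disp)
      expect_gte(t2$logFC[1], t1$logFC[1] - 1e-10)
    }
  })
})

test_that("Benjamini-Hochberg step-up behaves on edge cases", {
  expect_equal(adjust_bh(0.0123), 0.0123)
  expect_equal(adjust_bh(rep(0.04, 6)), rep(0.04, 6))
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("DEG filter applies strict thresholds on padj and |logFC|", {
  tab <- data.frame(gene = c("NOL4like", "weak", "boundary", "small_p"),
                    logFC = c(-5.14, 1.2, 3.0, 2.0),
                    padj = c(0.002490, 0.03, 0.05, 0.049))
  expect_equal(filter_degs(tab), c("NOL4like", "small_p"))
  expect_equal(filter_degs(tab, alpha = 0.06, min_abs_lfc = 1.1),
               c("NOL4like", "weak", "boundary", "small_p"))
})

test_that("null simulations keep the Wald test's size within bounds", {
  # small-n NB Wald is tolerated as mildly anti-conservative but bounded
  fracs <- vapply(1:20, function(r) {
    d <- make_two_group_counts(2000, 12, 3, mu = 100, dispersion = 0.1,
                               seed = 100 + r)
    tab <- run_diffexp(bud_counts(d$counts), cohort_samples())
    mean(tab$pvalue < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gte(median(fracs), 0.025)
  expect_lte(median(fracs), 0.10)
})
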