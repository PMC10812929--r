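test_that("FPKM follows counts * 1e9 / (length * library size)", {
  cnt <- matrix(c(100, 0, 10), 3, 1,
                dimnames = list(c("a", "b", "c"), "s1"))
  lens <- c(a = 2000, b = 500, c = 1000)
  expect_equal(unname(fpkm(cnt, lens, 1e7)[, 1]), c(5, 0, 1))
  expect_equal(unname(fpkm(cnt["c", , drop = FALSE], lens, 1e6)[, 1]), 10)
  expect_error(fpkm(cnt, c(a = 0, b = 500, c = 1000), 1e7), "> 0")
})

test_that("moment dispersion matches the pooled formula with a floor", {
  # Poisson-like: var <= mean in both groups -> floored
  es <- make_es(matrix(rep(c(9, 10, 11), 2), 1, 6, byrow = TRUE,
                       dimnames = list("f1", NULL)))
  expect_equal(estimate_dispersion(es)$dispersion, 1e-6)
  # mu = 10, s^2 = 100 in both groups -> (100 - 10) / 100 = 0.9
  es2 <- make_es(matrix(rep(c(0, 10, 20), 2), 1, 6, byrow = TRUE,
                        dimnames = list("f1", NULL)))
  expect_equal(estimate_dispersion(es2)$dispersion, 0.9)
  # all-zero features sit at the floor and are flagged
  es3 <- make_es(matrix(0, 1, 6, dimnames = list("f1", NULL)))
  d3 <- estimate_dispersion(es3)
  expect_equal(d3$dispersion, 1e-6)
  expect_true(d3$flagged)
})

test_that("moment dispersion recovers the simulated dispersion in distribution", {
  set.seed(7)
  cnt <- matrix(rnbinom(2000 * 6, mu = 100, size = 1 / 0.2), 2000, 6,
                dimnames = list(sprintf("f%04d", 1:2000), NULL))
  es <- make_es(cnt)
  med <- median(estimate_dispersion(es)$dispersion)
  expect_gte(med, 0.1)
  expect_lte(med, 0.4)
})

test_that("the NB exact test handles degenerate and closed-form cases", {
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), 0.3), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.3), 1)
  # Poisson limit: (0) vs (10) with equal libraries is the binomial split
  expect_equal(nb_exact_test(0, 10, 0), 2 * (1 / 2)^10)
  # and matches full enumeration of the 11 splits
  pr <- dbinom(0:10, 10, 0.5)
  expect_equal(nb_exact_test(0, 10, 0), sum(pr[pr <= pr[1]]))
  expect_error(nb_exact_test(c(1.5, 2), c(1, 1), 0.1), "integers")
})

test_that("swapping groups preserves p and negates the fold change", {
  set.seed(13)
  for (i in 1:20) {
    a <- rnbinom(3, mu = 60, size = 8); b <- rnbinom(3, mu = 140, size = 8)
    expect_equal(nb_exact_test(a, b, 0.12), nb_exact_test(b, a, 0.12))
  }
  cnt <- matrix(rnbinom(50 * 6, mu = 90, size = 10), 50, 6,
                dimnames = list(sprintf("f%02d", 1:50), NULL))
  es <- make_es(cnt)
  fwd <- de_test(es, "A", "B")
  rev <- de_test(es, "B", "A")
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$pvalue, rev$pvalue)
})

test_that("the exact test agrees with edgeR's exact test as an external check", {
  set.seed(21)
  cnt <- matrix(rnbinom(200 * 6, mu = 80, size = 10), 200, 6,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  d <- edgeR::DGEList(counts = cnt, group = rep(c("A", "B"), each = 3))
  d$samples$norm.factors <- 1
  d$samples$lib.size <- rep(1e6, 6)
  ref <- edgeR::exactTest(d, dispersion = 0.1)$table$PValue
  mine <- apply(cnt, 1, function(x) nb_exact_test(x[1:3], x[4:6], 0.1))
  expect_lt(max(abs(ref - mine)), 1e-8)
})

test_that("BH adjustment reproduces the step-up formula and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(4)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("status calls use strict thresholds on both axes", {
  res <- data.frame(log2fc = c(2, 0.5, -3, 1, 1.2),
                    qvalue = c(0.01, 0.001, 0.04, 0.01, 0.05))
  out <- call_de(res)
  expect_equal(out$status, c("up", "ns", "down", "ns", "ns"))
})

test_that("planted fold changes are detected with controlled error", {
  set.seed(3)
  nf <- 2000; n <- 3
  de <- seq_len(nf) <= nf * 0.1
  lfc <- ifelse(de, sample(c(-2, 2), nf, TRUE), 0)
  cnt <- matrix(0, nf, 2 * n, dimnames = list(sprintf("f%04d", 1:nf), NULL))
  for (j in seq_len(2 * n)) {
    m <- 100 * (if (j > n) 2^lfc else 1)
    cnt[, j] <- rnbinom(nf, mu = m, size = 10)
  }
  res <- de_test(make_es(cnt))
  called <- res$status != "ns"
  expect_gte(mean(called[de]), 0.8)                 # sensitivity
  expect_lte(mean(!de[called]), 0.1)                # empirical FDR
  # direction is recovered
  expect_true(all(res$status[de & lfc > 0 & called] == "up"))
})
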