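lnc1 <- data.frame(lncrna_id = "L1", chrom = "chr1", start = 200000, end = 201000)

test_that("cis targets use inter-span gaps within the window", {
  genes <- data.frame(gene_id = c("gNear", "gFar", "gOver"),
                      chrom = "chr1",
                      start = c(250000, 350000, 200500),
                      end = c(252000, 352000, 202000))
  ct <- cis_targets(lnc1, genes, window = 100000)
  expect_equal(sort(ct$gene_id), c("gNear", "gOver"))
  expect_equal(ct$distance[ct$gene_id == "gNear"], 49000)
  expect_equal(ct$distance[ct$gene_id == "gOver"], 0)
  # distance is symmetric in the two spans
  swapped <- cis_targets(
    data.frame(lncrna_id = "gNear", chrom = "chr1", start = 250000, end = 252000),
    data.frame(gene_id = "L1", chrom = "chr1", start = 200000, end = 201000))
  expect_equal(swapped$distance, 49000)
  # enlarging the window never removes a pair
  wider <- cis_targets(lnc1, genes, window = 200000)
  expect_true(all(paste(ct$lncrna_id, ct$gene_id) %in%
                    paste(wider$lncrna_id, wider$gene_id)))
  expect_equal(nrow(cis_targets(lnc1, genes[0, ], 1e5)), 0)
})

test_that("pearson matches closed-form endpoints and rejects degenerate input", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)
  out <- pearson(c(1, 2, 3, 5), c(2, 3, 7, 8))
  ref <- cor.test(c(1, 2, 3, 5), c(2, 3, 7, 8))
  expect_equal(out$pvalue, ref$p.value)
  expect_error(pearson(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(pearson(1:3, 1:4), "length")
})

test_that("trans targets keep |r| >= cutoff with p < alpha, boundary inclusive", {
  lnc <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("L1", sprintf("s%d", 1:6)))
  genes <- rbind(L1x2 = 2 * lnc[1, ], flat = c(5, 5, 5, 5, 5, 6))
  colnames(genes) <- colnames(lnc)
  tp <- trans_targets(lnc, genes, min_abs_r = 1, alpha = 0.05)
  expect_equal(tp$gene_id, "L1x2")   # r exactly 1 kept at the boundary
  expect_equal(tp$r, 1)
  expect_error(trans_targets(lnc, genes[, 1:5]), "sample columns")
  const <- rbind(constant = rep(3, 6)); colnames(const) <- colnames(lnc)
  expect_warning(trans_targets(lnc, const), "constant")
})

test_that("planted co-expression pairs are recovered with few decoys", {
  ex <- coexpression_experiment(seed = 9)
  tp <- trans_targets(ex$lnc_expr, ex$gene_expr)
  key <- paste(tp$lncrna_id, tp$gene_id)
  planted <- paste(ex$planted$lncrna_id, ex$planted$gene_id)
  expect_true(all(planted %in% key))
  n_decoy_pairs <- nrow(ex$lnc_expr) * nrow(ex$gene_expr) - length(planted)
  expect_lte(sum(!key %in% planted) / n_decoy_pairs, 0.05)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  tm <- data.frame(term_id = "T1", gene_id = sprintf("g%02d", 1:5))
  universe <- sprintf("g%02d", 1:20)
  res <- enrich(sprintf("g%02d", 1:10), universe, tm)
  expect_equal(res$pvalue, 3003 / 184756, tolerance = 1e-12)
  expect_equal(res$k, 5)
  # k = 0 spans the whole support
  res0 <- enrich(sprintf("g%02d", 11:20), universe,
                 data.frame(term_id = "T1", gene_id = sprintf("g%02d", 1:5)))
  expect_equal(res0$pvalue, 1)
  # selected == universe forces k == K and p == 1 for every term
  tm2 <- data.frame(term_id = rep(c("T1", "T2"), c(4, 7)),
                    gene_id = c(sprintf("g%02d", 1:4), sprintf("g%02d", 6:12)))
  resU <- enrich(universe, universe, tm2)
  expect_true(all(resU$pvalue == 1))
  expect_equal(resU$k, resU$K)
  expect_error(enrich(c("g01", "zz"), universe, tm), "subset")
})

test_that("edge export mirrors the pair table and annotates DE status", {
  pairs <- data.frame(lncrna_id = c("L1", "L2"), gene_id = c("g1", "g2"),
                      mode = c("cis", "trans"), distance = c(100, NA),
                      r = c(NA, 0.99))
  de <- data.frame(feature_id = c("L1", "g1"), status = c("up", "down"))
  p <- withr::local_tempfile(fileext = ".tsv")
  edges <- export_network(pairs, de, p)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$source_status, c("up", NA))
  expect_equal(edges$target_status, c("down", NA))
  expect_true(file.exists(p))
  # empty set -> header-only file
  export_network(pairs[0, ], de, p)
  expect_equal(length(readLines(p)), 1)
})
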