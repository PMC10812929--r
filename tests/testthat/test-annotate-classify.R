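ref_small <- rbind(
  tx("r1", "chr1", "+", c(1000, 1800), c(1200, 2000), gene = "gA"),
  tx("r2", "chr2", "+", 1400, 1700, gene = "gB")
)

test_that("exonic overlap sums pairwise intersections and is symmetric", {
  a <- tx("q", "chr1", "+", 100, 200)
  b <- tx("s", "chr1", "+", 150, 250)
  expect_equal(exonic_overlap_bp(a, b), 50)
  expect_equal(exonic_overlap_bp(b, a), 50)
  expect_equal(exonic_overlap_bp(a, tx("s", "chr1", "+", 300, 400)), 0)
  expect_equal(exonic_overlap_bp(a, tx("s", "chr2", "+", 150, 250)), 0)
  chain <- tx("q", "chr1", "+", c(0, 300), c(100, 450))
  expect_equal(exonic_overlap_bp(chain, chain), 250)
})

test_that("class codes follow the = > o > i > x > u decision procedure", {
  idx <- build_reference_index(ref_small)
  classify1 <- function(t) classify_transcripts(t, idx)$code
  # no overlap with anything -> intergenic
  expect_equal(classify1(tx("q1", "chr1", "+", 5000, 5500)), "u")
  # opposite-strand exonic overlap -> antisense
  expect_equal(classify1(tx("q2", "chr2", "-", 1500, 1600)), "x")
  # fully inside a same-strand intron -> intronic
  expect_equal(classify1(tx("q3", "chr1", "+", 1300, 1700)), "i")
  # same-strand exonic overlap -> sense
  expect_equal(classify1(tx("q4", "chr1", "+", 1100, 1300)), "o")
  # identical exon chain -> annotated, and it outranks 'o'
  expect_equal(classify1(tx("q5", "chr1", "+", c(1000, 1800), c(1200, 2000))), "=")
  # sense overlap outranks antisense when both exist
  both <- rbind(ref_small, tx("r3", "chr2", "-", 1400, 1700, gene = "gC"))
  expect_equal(classify_transcripts(tx("q6", "chr2", "+", 1500, 1600),
                                    build_reference_index(both))$code, "o")
  # subject gene recorded except for intergenic
  cc <- classify_transcripts(tx("q4", "chr1", "+", 1100, 1300), idx)
  expect_equal(cc$subject_gene_id, "gA")
  expect_equal(classify_transcripts(tx("q1", "chr1", "+", 5000, 5500),
                                    idx)$subject_gene_id, "")
})

test_that("unstranded queries are rejected with a warning, not an error", {
  idx <- build_reference_index(ref_small)
  q <- rbind(tx("q1", "chr1", ".", 5000, 5500), tx("q2", "chr1", "+", 5000, 5500))
  expect_warning(cc <- classify_transcripts(q, idx), "unstranded")
  expect_equal(cc$transcript_id, "q2")
})

test_that("indexed classifier agrees with the brute-force oracle on random inputs", {
  cfg <- synth_config(seed = 7)
  ann <- generate_annotation(cfg)
  nov <- generate_novel_transcripts(cfg, ann)
  expect_gte(nrow(nov$truth), 200)
  codes <- classify_transcripts(nov$exons, build_reference_index(ann$exons))
  oracle <- brute_force_classify(nov$exons, ann$exons)
  expect_equal(codes$code, unname(oracle[codes$transcript_id]))
  # exactly one code per transcript; codes partition the input
  expect_equal(sort(codes$transcript_id), sort(unique(nov$truth$transcript_id)))
  expect_equal(sum(table(codes$code)), nrow(nov$truth))
  # 'u' transcripts have no exonic overlap and no gene-span containment
  rst <- transcript_stats(ann$exons)
  for (tid in sample(codes$transcript_id[codes$code == "u"], 10)) {
    qx <- nov$exons[nov$exons$transcript_id == tid, ]
    qs <- transcript_stats(qx)
    for (rt in rst$transcript_id[rst$chrom == qs$chrom]) {
      rx <- ann$exons[ann$exons$transcript_id == rt, ]
      expect_equal(exonic_overlap_bp(qx, rx), 0)
      rs <- rst[rst$transcript_id == rt, ]
      expect_false(qs$start >= rs$start && qs$end <= rs$end)
    }
  }
})

test_that("chromosome density bins features by start and conserves totals", {
  f <- data.frame(chrom = "chr1", start = c(0, 10, 1e6))
  d <- chromosome_density(f, c(chr1 = 2e6), bin_size = 1e6)
  expect_equal(d$count, c(2, 1))
  expect_equal(chromosome_density(f[0, ], c(chr1 = 2e6), 1e6)$count, c(0, 0))
  set.seed(3)
  f2 <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                   start = sample.int(2e6, 100) - 1)
  d2 <- chromosome_density(f2, c(chr1 = 2e6, chr2 = 2e6), 123456)
  expect_equal(sum(d2$count), 100)
  expect_warning(
    d3 <- chromosome_density(data.frame(chrom = c("chr1", "chrX"), start = c(0, 0)),
                             c(chr1 = 1e6), 1e5),
    "unknown chromosome")
  expect_equal(sum(d3$count), 1)
})
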