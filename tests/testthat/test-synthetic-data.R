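small_cfg <- function(seed = 2) {
  synth_config(seed = seed, n_ref_genes = 40,
               n_novel = c(u = 30, x = 12, i = 6, o = 10, "=" = 8),
               n_planted_homologs = 8, n_oneway_homologs = 3,
               n_decoy_hits = 20, n_trans_pairs = 5, n_training = 60)
}

test_that("the whole bundle is a pure function of the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_bundle(small_cfg(), d1)
  generate_bundle(small_cfg(), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_bundle(small_cfg(seed = 3), d3)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
})

test_that("reference gene spans never overlap and empty annotations are valid", {
  ann <- generate_annotation(synth_config(seed = 5))
  st <- transcript_stats(ann$exons)
  for (ch in unique(st$chrom)) {
    s <- st[st$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  empty <- generate_annotation(synth_config(seed = 5, n_ref_genes = 0))
  expect_equal(nrow(empty$exons), 0)
})

test_that("planted class counts match the configuration", {
  cfg <- small_cfg()
  nov <- generate_novel_transcripts(cfg, generate_annotation(cfg))
  expect_equal(as.list(table(nov$truth$class)),
               list("=" = 8L, i = 6L, o = 10L, u = 30L, x = 12L))
})

test_that("planted coding sequences host long ORFs; classes stay GC-matched", {
  cfg <- small_cfg()
  nov <- generate_novel_transcripts(cfg, generate_annotation(cfg))
  sq <- generate_sequences(cfg, nov$truth)
  coding <- sq$seqs[nov$truth$coding & nov$truth$length >= 450]
  expect_true(all(vapply(coding, function(s) longest_orf(s)$length,
                         numeric(1)) >= 300))
  gc <- function(x) {
    b <- strsplit(paste(x, collapse = ""), "")[[1]]
    mean(b %in% c("G", "C"))
  }
  nc <- sq$seqs[!nov$truth$coding]
  expect_lt(abs(gc(coding) - gc(nc)), 0.05)
  # same seed gives identical sequences
  sq2 <- generate_sequences(cfg, nov$truth)
  expect_identical(sq$seqs, sq2$seqs)
})

test_that("count generation honors the DE configuration and seed", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  nov <- generate_novel_transcripts(cfg, ann)
  rst <- transcript_stats(ann$exons)
  lengths <- c(stats::setNames(nov$truth$length, nov$truth$transcript_id),
               stats::setNames(rst$length, rst$gene_id))
  genes <- sort(unique(rst$gene_id))
  cnt <- generate_counts(cfg, nov$truth, lengths, genes)
  cnt2 <- generate_counts(cfg, nov$truth, lengths, genes)
  expect_identical(cnt$es$counts, cnt2$es$counts)
  # de_fraction = 0 plants no DE features
  cfg0 <- small_cfg(); cfg0$de_fraction <- 0
  cnt0 <- generate_counts(cfg0, nov$truth, lengths, genes)
  expect_true(all(cnt0$de_truth$status %in% c("ns", "derived")))
  expect_true(all(cnt0$de_truth$lfc == 0))
})

test_that("planted fold changes materialize in the realized group means", {
  cfg <- synth_config(seed = 6, n_ref_genes = 40,
                      n_novel = c(u = 60, x = 0, i = 0, o = 0, "=" = 0),
                      de_fraction = 0.5, low_expr_fraction = 0,
                      n_trans_pairs = 0)
  ann <- generate_annotation(cfg)
  nov <- generate_novel_transcripts(cfg, ann)
  rst <- transcript_stats(ann$exons)
  lengths <- c(stats::setNames(nov$truth$length, nov$truth$transcript_id),
               stats::setNames(rst$length, rst$gene_id))
  cnt <- generate_counts(cfg, nov$truth, lengths, sort(unique(rst$gene_id)))
  es <- cnt$es
  ratio <- rowMeans(es$counts[, es$groups == "FF"]) /
    pmax(1e-9, rowMeans(es$counts[, es$groups == "FB"]))
  up <- cnt$de_truth$feature_id[cnt$de_truth$status == "up"]
  ns <- cnt$de_truth$feature_id[cnt$de_truth$status == "ns"]
  # planted |lfc| = 2 -> FF/FB around 4 for 'up', around 1 for 'ns'
  expect_gt(median(ratio[up]), 2.5)
  expect_lt(median(ratio[up]), 6)
  expect_gt(median(ratio[ns]), 0.7)
  expect_lt(median(ratio[ns]), 1.4)
})

test_that("fabricated homology tables recover exactly the planted structure", {
  cfg <- small_cfg()
  set.seed(99)
  lnc_seqs <- stats::setNames(
    replicate(30, paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")),
    sprintf("LNC%03d", 1:30))
  hom <- generate_homology(cfg, lnc_seqs)
  qlen <- nchar(lnc_seqs)
  for (sp in names(hom$forward)) {
    f <- hom$forward[[sp]]
    if (nrow(f) == 0) next
    f$query_length <- qlen[f$query_id]
    kept <- filter_hits(f)
    planted_here <- hom$conserved_truth$query_id[hom$conserved_truth$species == sp]
    expect_setequal(unique(kept$query_id), planted_here)
    # planted rows meet both filters by construction
    expect_true(all(kept$coverage >= 0.3 & kept$evalue < 1e-10))
  }
  expect_error(generate_homology(synth_config(mutation_rate = 0.6), lnc_seqs),
               "unrecoverable")
})

test_that("every generated artifact parses cleanly with the package readers", {
  bundle <- default_bundle_dir()
  expect_no_warning({
    ref <- read_gtf(file.path(bundle, "reference.gtf"))
    nov <- read_gtf(file.path(bundle, "novel.gtf"))
    seqs <- read_fasta(file.path(bundle, "novel.fa"))
    es <- read_counts(file.path(bundle, "counts.tsv"),
                      file.path(bundle, "samples.tsv"))
  })
  expect_setequal(names(seqs), unique(nov$transcript_id))
  expect_equal(ncol(es$counts), 6)
  expect_setequal(unique(es$groups), c("FB", "FF"))
  sp_files <- list.files(file.path(bundle, "homology"), pattern = "_forward")
  expect_gt(length(sp_files), 0)
  for (f in sp_files) {
    sp <- sub("_forward\\.tsv$", "", f)
    expect_no_warning(read_blast_tab(file.path(bundle, "homology", f),
                                     nchar(seqs)))
  }
})
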