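test_that("longest ORF scan matches direct cases and brute-force enumeration", {
  o <- longest_orf("ATGGCCTAA")
  expect_equal(o$start, 0)
  expect_equal(o$length, 9)
  expect_true(o$has_stop)
  expect_equal(longest_orf("CCCCCC")$length, 0)
  expect_equal(longest_orf("")$length, 0)
  # frame-0 ORF subsumes the inner ATG
  o2 <- longest_orf("ATGATGTAA")
  expect_equal(o2$start, 0)
  expect_equal(o2$length, 9)
  # open-ended ORF without a downstream stop
  o3 <- longest_orf("ATGAAAAA")
  expect_false(o3$has_stop)
  expect_equal(o3$length, 6)
  # brute-force (start, stop) enumeration on random sequences
  set.seed(11)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:400, 1), TRUE),
               collapse = "")
    expect_equal(longest_orf(s)$length, brute_force_orf_length(s), info = s)
  }
})

test_that("Fickett score is deterministic and matches a hand-applied table lookup", {
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_identical(fickett_score(s), fickett_score(s))
  # hand application for "A"x60: every position parameter is max/(min+1) =
  # 20/21 (lowest bin), content is 1 for A (top bin) and 0 elsewhere
  hand <- 0.22 * 0.26 + 0.23 * 0.18 + 0.08 * 0.31 + 0.09 * 0.33 +
    0.28 * 0.11 + 0.31 * 0.12 + 0.29 * 0.15 + 0.58 * 0.14
  expect_equal(as.numeric(fickett_score(strrep("A", 60))), hand)
  expect_true(attr(fickett_score(strrep("A", 60)), "low_confidence"))
  expect_true(attr(fickett_score(paste0(strrep("N", 50), strrep("A", 60))), "high_n"))
})

test_that("codon-biased CDS outscores its composition-preserving shuffle", {
  set.seed(42)
  mk_cds <- function() paste0(
    "ATG",
    paste(sample(lncid:::.synth_codons, 98, TRUE, prob = lncid:::.synth_codon_w),
          collapse = ""),
    "TAA")
  wins <- replicate(200, {
    s <- mk_cds()
    as.numeric(fickett_score(s)) > as.numeric(fickett_score(markov_shuffle(s)))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("hexamer model training counts, smooths and normalizes", {
  m <- train_hexamer_model("AAAAAA", pseudocount = 1)
  expect_equal(unname(m["AAAAAA"]), 2 / 4097)
  expect_equal(unname(m["ACGTAC"]), 1 / 4097)
  expect_equal(sum(m), 1)
  set.seed(8)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  expect_equal(sum(train_hexamer_model(seqs)), 1)
  # order invariance
  expect_identical(unclass(train_hexamer_model(seqs)),
                   unclass(train_hexamer_model(rev(seqs))))
  expect_error(train_hexamer_model(character(0)), "empty")
})

test_that("hexamer LLR has the closed-form value, antisymmetry and zero point", {
  uniform <- structure(stats::setNames(rep(1 / 4096, 4096),
                                       names(train_hexamer_model("ACGTAC"))),
                       class = "hexamer_model")
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  expect_equal(as.numeric(hexamer_llr(s, uniform, uniform)), 0)
  # models sharing a denominator, one hexamer enriched 2x in coding
  w <- rep(1, 4096); names(w) <- names(uniform)
  cm <- w; cm["ACGACG"] <- 2; cm <- structure(cm / sum(cm), class = "hexamer_model")
  nm <- w; nm["TGCTGC"] <- 2; nm <- structure(nm / sum(nm), class = "hexamer_model")
  rep_acg <- strrep("ACG", 30)  # every step-3 window is ACGACG
  expect_equal(as.numeric(hexamer_llr(rep_acg, cm, nm)), log(2))
  expect_equal(as.numeric(hexamer_llr(rep_acg, nm, cm)),
               -as.numeric(hexamer_llr(rep_acg, cm, nm)))
  short <- hexamer_llr("ACGT", cm, nm)
  expect_equal(as.numeric(short), 0)
  expect_true(attr(short, "too_short"))
})

test_that("intersection vote requires unanimity and is monotone", {
  sc <- data.frame(transcript_id = c("a", "b", "c"),
                   orf_length = c(100, 100, 400),
                   fickett = c(0.5, 0.5, 0.5),
                   hexamer_llr = c(-1, -1, -1))
  v <- ensemble_noncoding_vote(sc)
  expect_equal(v$is_noncoding, c(TRUE, TRUE, FALSE))
  # raising any single score to a coding call can only remove lncRNA status
  set.seed(6)
  for (i in 1:50) {
    base <- data.frame(transcript_id = "t",
                       orf_length = sample(0:600, 1),
                       fickett = runif(1, 0, 1.3),
                       hexamer_llr = runif(1, -2, 2))
    v0 <- ensemble_noncoding_vote(base)$is_noncoding
    bump <- base
    col <- sample(c("orf_length", "fickett", "hexamer_llr"), 1)
    bump[[col]] <- c(orf_length = 1000, fickett = 2, hexamer_llr = 5)[[col]]
    v1 <- ensemble_noncoding_vote(bump)$is_noncoding
    expect_false(!v0 && v1)
  }
  expect_error(ensemble_noncoding_vote(sc[, 1:3]), "missing predictor")
})

test_that("the built-in ensemble recovers planted coding labels", {
  bundle <- default_bundle_dir()
  truth <- read_truth("classes.tsv")
  cm <- train_hexamer_model(read_fasta(file.path(bundle, "training_coding.fa")))
  nm <- train_hexamer_model(read_fasta(file.path(bundle, "training_noncoding.fa")))
  seqs <- read_fasta(file.path(bundle, "novel.fa"))
  v <- ensemble_noncoding_vote(score_coding_potential(seqs, cm, nm))
  m <- merge(v, truth, by = "transcript_id")
  acc <- mean(m$is_noncoding == !m$coding)
  expect_gte(acc, 0.90)
  # false-coding rate on planted lncRNAs
  planted_nc <- m[!m$coding, ]
  expect_lte(mean(!planted_nc$is_noncoding), 0.15)
})

test_that("external predictor tables are ingested with the stated contracts", {
  cpc2 <- data.frame(id = c("t1", "t2", "t3"),
                     label = c("noncoding", "coding", "noncoding"))
  cnci <- data.frame(id = c("t1", "t2", "t3"), score = c(-1.2, 0.4, -0.5))
  pfam <- data.frame(transcript_id = c("t1", "t2"), hit = c("-", "PF00001"))
  expect_warning(v <- ingest_external_predictions(cpc2, cnci, pfam), "t3")
  expect_equal(v$transcript_id, c("t1", "t2"))
  expect_equal(v$is_noncoding, c(TRUE, FALSE))
  expect_false(v$call_pfam[1])  # '-' means no hit
  expect_true(v$call_pfam[2])   # any hit -> coding
  cpc2_bad <- data.frame(id = "t1", label = "maybe")
  expect_error(ingest_external_predictions(cpc2_bad, cnci, pfam), "t1")
})
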