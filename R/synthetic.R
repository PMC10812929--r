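#' Configuration for the synthetic data generator
#'
#' The generator emulates a two-stage (flower bud FB vs full-bloom FF,
#' three biological replicates each) stranded RNA-seq study of a small
#' diploid genome: a reference annotation, novel transcripts planted to
#' satisfy each positional class, transcript sequences with planted coding
#' or non-coding character, negative-binomial counts with planted fold
#' changes, fabricated cross-species homology hit tables with planted
#' reciprocal-best-hit pairs, and a term map for enrichment. Everything is
#' a pure function of this configuration; the same seed yields
#' byte-identical files.
#'
#' Default scale (2 chromosomes x 2 Mb, 100 reference genes, 400 novel
#' transcripts) keeps every stage in the seconds range while leaving each
#' planted feature class populous enough to measure recovery. Length and
#' exon-count defaults mirror the usual plant lncRNA/mRNA contrast
#' (lncRNA-like ~800 nt, mostly 1-2 exons; mRNA-like ~2900 nt, ~5 exons).
#'
#' @param seed Integer seed driving every random choice.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_ref_genes Reference (protein-coding) genes, placed without
#'   overlap on both strands.
#' @param n_novel Named counts of planted novel transcripts per positional
#'   class (`u`, `x`, `i`, `o`, `=`).
#' @param coding_fraction Fraction of novel transcripts planted as coding.
#' @param lnc_length_mean,mrna_length_mean Mean transcript lengths (nt) of
#'   the two planted sequence classes.
#' @param n_samples Replicates per condition.
#' @param groups The two condition labels.
#' @param mu Median baseline expression (counts) of a feature.
#' @param dispersion NB dispersion phi (variance mu + phi mu^2).
#' @param de_fraction Fraction of features planted as differentially
#'   expressed.
#' @param de_log2fc Planted |log2 fold change|.
#' @param low_expr_fraction Fraction of planted lncRNAs given negligible
#'   expression (to exercise the FPKM filter).
#' @param short_fraction Fraction of planted intergenic lncRNAs made
#'   shorter than 200 nt (to exercise the length filter).
#' @param n_species,n_planted_homologs,n_oneway_homologs,n_decoy_hits
#'   Homology-table shape: species count, reciprocal planted pairs,
#'   one-way-only conserved queries, and decoy hit rows that must not pass
#'   the filters.
#' @param mutation_rate Per-base substitution rate of planted homolog
#'   copies (must be < 0.5 or pairs become unrecoverable).
#' @param n_trans_pairs Planted co-expressed lncRNA-gene pairs.
#' @param n_terms Annotation terms in the fabricated term map.
#' @param n_training Sequences per class in the hexamer training corpora.
#' @return Named list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_chromosomes = 2, chrom_length = 2e6,
                         n_ref_genes = 100,
                         n_novel = c(u = 180, x = 80, i = 20, o = 60, "=" = 60),
                         coding_fraction = 0.25,
                         lnc_length_mean = 800, mrna_length_mean = 2900,
                         n_samples = 3, groups = c("FB", "FF"),
                         mu = 200, dispersion = 0.1,
                         de_fraction = 0.3, de_log2fc = 2,
                         low_expr_fraction = 0.1, short_fraction = 0.05,
                         n_species = 5, n_planted_homologs = 30,
                         n_oneway_homologs = 10, n_decoy_hits = 100,
                         mutation_rate = 0.1,
                         n_trans_pairs = 20, n_terms = 20,
                         n_training = 150) {
  stopifnot(seed == round(seed), n_chromosomes >= 1, chrom_length > 0,
            n_ref_genes >= 0, all(n_novel >= 0),
            coding_fraction >= 0, coding_fraction <= 1,
            n_samples >= 2, length(groups) == 2L,
            mu > 0, dispersion >= 0, de_fraction >= 0, de_fraction <= 1,
            low_expr_fraction >= 0, low_expr_fraction <= 1,
            n_species >= 1, n_planted_homologs >= 0)
  if (mutation_rate >= 0.5) {
    stop("mutation_rate >= 0.5: planted homolog pairs would be unrecoverable")
  }
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# ---------------------------------------------------------------- annotation

#' Generate a reference annotation
#'
#' Places multi-exon genes on both strands, in per-chromosome slots so
#' that gene spans never overlap (across strands too).
#'
#' @param config A [synth_config()].
#' @return List with `exons` (exon table) and `chrom_sizes` (named vector).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed + 101L)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(config$chrom_length, length(chroms)), chroms)
  n <- config$n_ref_genes
  if (n == 0L) {
    return(list(exons = empty_exon_table(), chrom_sizes = chrom_sizes))
  }
  per_chrom <- diff(round(seq(0, n, length.out = length(chroms) + 1L)))
  rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    n_c <- per_chrom[ci]
    if (n_c == 0L) next
    slot <- floor(config$chrom_length / n_c)
    for (k in seq_len(n_c)) {
      gi <- gi + 1L
      n_ex <- sample(3:8, 1L)
      ex_len <- sample(100:300, n_ex, replace = TRUE)
      in_len <- sample(400:2000, max(0L, n_ex - 1L), replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      slot_start <- (k - 1L) * slot
      margin <- max(200L, floor(0.1 * slot))
      free <- slot - span - 2L * margin
      if (free < 1L) stop("reference genes do not fit the chromosome; ",
                          "reduce n_ref_genes or gene sizes")
      g_start <- slot_start + margin + sample.int(free, 1L)
      starts <- g_start + cumsum(c(0L, utils::head(ex_len, -1L) + in_len))
      rows[[gi]] <- data.frame(
        transcript_id = sprintf("JSG%05d.t1", gi),
        gene_id = sprintf("JSG%05d", gi),
        chrom = chroms[ci],
        strand = sample(c("+", "-"), 1L),
        start = starts, end = starts + ex_len,
        stringsAsFactors = FALSE
      )
    }
  }
  exons <- canonical_exon_order(do.call(rbind, rows))
  list(exons = exons, chrom_sizes = chrom_sizes)
}

# ------------------------------------------------------- novel transcripts

#' Generate novel transcripts with planted positional classes
#'
#' Each requested class is constructed to satisfy its defining relation:
#' `u` placed in intergenic gaps, `x` overlapping a reference exon on the
#' opposite strand, `i` contained in an intron of a same-strand reference
#' transcript, `o` overlapping a reference exon on the same strand, and
#' `=` as exact exon-chain copies. Coding flags are planted on a
#' `coding_fraction` of the `u`/`x`/`i`/`o` transcripts that are long
#' enough to host a 300-nt ORF (planted coding intergenic transcripts get
#' mRNA-like multi-exon structures); a `short_fraction` of the non-coding
#' intergenic transcripts is made shorter than 200 nt.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @return List with `exons` (exon table of the novel transcripts) and
#'   `truth` (`transcript_id`, `class`, `coding`, `short`, `length`).
#' @export
generate_novel_transcripts <- function(config, annotation) {
  set.seed(config$seed + 202L)
  ref <- annotation$exons
  rst <- transcript_stats(ref)
  ref_by_tx <- split(ref[c("start", "end")],
                     factor(ref$transcript_id, levels = rst$transcript_id))
  chrom_sizes <- annotation$chrom_sizes
  gaps <- intergenic_gaps(rst, chrom_sizes)

  rows <- list(); truth <- list(); idx <- 0L
  add <- function(exdf, class, coding, short = FALSE) {
    idx <<- idx + 1L
    tid <- sprintf("NOV%05d", idx)
    exdf$transcript_id <- tid
    exdf$gene_id <- sprintf("NOVG%05d", idx)
    rows[[idx]] <<- exdf[, c("transcript_id", "gene_id", "chrom", "strand",
                             "start", "end")]
    truth[[idx]] <<- data.frame(
      transcript_id = tid, class = class, coding = coding, short = short,
      length = sum(exdf$end - exdf$start), stringsAsFactors = FALSE)
  }
  lnc_len <- function(lo = 250, hi = 3000) {
    round(min(hi, max(lo, stats::rlnorm(1L,
      meanlog = log(config$lnc_length_mean) - 0.45^2 / 2, sdlog = 0.45))))
  }

  # intergenic ('u')
  n_u <- config$n_novel[["u"]]
  n_u_coding <- round(config$coding_fraction * n_u)
  n_u_short <- round(config$short_fraction * (n_u - n_u_coding))
  for (k in seq_len(n_u)) {
    coding <- k <= n_u_coding
    short <- !coding && k <= n_u_coding + n_u_short
    if (coding) {
      len <- round(min(8000, max(450, stats::rlnorm(1L,
        meanlog = log(config$mrna_length_mean) - 0.35^2 / 2, sdlog = 0.35))))
      n_ex <- sample(3:7, 1L)
    } else if (short) {
      len <- sample(120:180, 1L); n_ex <- 1L
    } else {
      len <- lnc_len(); n_ex <- sample(1:2, 1L, prob = c(0.75, 0.25))
    }
    ex <- random_exon_chain(len, n_ex)
    placed <- place_in_gaps(gaps, span = max(ex$end), margin = 200L)
    if (is.null(placed)) stop("no intergenic gap fits a planted transcript; ",
                              "enlarge the genome or shrink transcripts")
    add(data.frame(chrom = placed$chrom, strand = sample(c("+", "-"), 1L),
                   start = ex$start + placed$offset, end = ex$end + placed$offset,
                   stringsAsFactors = FALSE),
        class = "u", coding = coding, short = short)
  }

  # antisense ('x') and sense ('o'): single exon overlapping a reference exon
  for (class in c("x", "o")) {
    n_c <- config$n_novel[[class]]
    for (k in seq_len(n_c)) {
      j <- sample.int(nrow(rst), 1L)
      rex <- ref_by_tx[[j]]
      e <- rex[sample.int(nrow(rex), 1L), ]
      coding <- stats::runif(1L) < config$coding_fraction
      len <- if (coding) sample(450:1400, 1L) else max(200L, min(1400L, lnc_len()))
      ov <- sample(50:min(len, e$end - e$start), 1L)
      n_start <- e$end - ov
      strand <- if (class == "x") flip_strand(rst$strand[j]) else rst$strand[j]
      add(data.frame(chrom = rst$chrom[j], strand = strand,
                     start = n_start, end = n_start + len,
                     stringsAsFactors = FALSE),
          class = class, coding = coding)
    }
  }

  # intronic ('i'): single exon inside an intron, same strand
  n_i <- config$n_novel[["i"]]
  multi <- which(vapply(ref_by_tx, nrow, integer(1)) >= 2L)
  for (k in seq_len(n_i)) {
    repeat {
      j <- sample(multi, 1L)
      rex <- ref_by_tx[[j]]
      istart <- rex$end[-nrow(rex)]; iend <- rex$start[-1L]
      wide <- which(iend - istart >= 300L)
      if (length(wide)) break
    }
    w <- wide[sample.int(length(wide), 1L)]
    avail <- iend[w] - istart[w] - 40L
    len <- min(avail, max(200L, lnc_len()))
    coding <- len >= 450 && stats::runif(1L) < config$coding_fraction
    n_start <- istart[w] + 20L + sample.int(max(1L, avail - len), 1L)
    add(data.frame(chrom = rst$chrom[j], strand = rst$strand[j],
                   start = n_start, end = n_start + len,
                   stringsAsFactors = FALSE),
        class = "i", coding = coding)
  }

  # annotated ('='): exact exon-chain copies
  n_eq <- config$n_novel[["="]]
  for (k in seq_len(n_eq)) {
    j <- sample.int(nrow(rst), 1L)
    rex <- ref_by_tx[[j]]
    add(data.frame(chrom = rst$chrom[j], strand = rst$strand[j],
                   start = rex$start, end = rex$end, stringsAsFactors = FALSE),
        class = "=", coding = TRUE)
  }

  exons <- canonical_exon_order(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(exons = exons, truth = truth)
}

flip_strand <- function(s) if (s == "+") "-" else "+"

# exon chain of total exonic length len with n_ex exons, 0-based at 0
random_exon_chain <- function(len, n_ex) {
  if (n_ex == 1L) return(data.frame(start = 0L, end = len))
  cuts <- sort(sample.int(len - 1L, n_ex - 1L))
  ex_len <- diff(c(0L, cuts, len))
  while (any(ex_len < 30L)) {  # avoid degenerate slivers
    cuts <- sort(sample.int(len - 1L, n_ex - 1L))
    ex_len <- diff(c(0L, cuts, len))
  }
  in_len <- sample(100:1500, n_ex - 1L, replace = TRUE)
  starts <- cumsum(c(0L, utils::head(ex_len, -1L) + in_len))
  data.frame(start = starts, end = starts + ex_len)
}

# per-chromosome complement of the reference gene spans
intergenic_gaps <- function(rst, chrom_sizes) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    spans <- rst[rst$chrom == ch, , drop = FALSE]
    spans <- spans[order(spans$start), , drop = FALSE]
    bounds <- c(0, rbind(spans$start, spans$end), chrom_sizes[[ch]])
    gs <- bounds[seq(1, length(bounds), by = 2L)]
    ge <- bounds[seq(2, length(bounds), by = 2L)]
    keep <- ge > gs
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = gs[keep], end = ge[keep],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

place_in_gaps <- function(gaps, span, margin) {
  ok <- gaps[gaps$end - gaps$start >= span + 2 * margin, , drop = FALSE]
  if (nrow(ok) == 0L) return(NULL)
  w <- ok$end - ok$start
  g <- ok[sample.int(nrow(ok), 1L, prob = w), ]
  free <- (g$end - g$start) - span - 2 * margin
  offset <- g$start + margin + sample.int(max(1L, free), 1L)
  list(chrom = g$chrom, offset = offset)
}

# ------------------------------------------------------------- sequences

# codon pool with usage bias (weights) and ~48% GC, used for planted ORFs
.synth_codons <- c("GCT", "CGT", "AAC", "GAT", "TGC", "CAA", "GAA", "GGT",
                   "CAC", "ATC", "CTT", "AAG", "TTC", "CCA", "TCT", "ACC",
                   "TAC", "GTG", "TGG", "ATG")
.synth_codon_w <- c(4, 1, 4, 1, 1, 1, 1, 4, 1, 1, 4, 1, 1, 1, 1, 4, 1, 1, 1, 1)
.synth_nc_prob <- c(A = 0.26, C = 0.24, G = 0.24, T = 0.26)

random_noncoding_seq <- function(len, stop_spacing = 55L) {
  s <- sample(names(.synth_nc_prob), len, replace = TRUE, prob = .synth_nc_prob)
  # plant stop codons at staggered frames so no frame keeps a long ORF
  pos <- 1L
  while (pos + 2L <= len - 3L) {
    pos <- pos + sample(seq(stop_spacing - 20L, stop_spacing + 20L), 1L)
    if (pos + 2L > len) break
    s[pos:(pos + 2L)] <- strsplit(sample(c("TAA", "TAG", "TGA"), 1L), "")[[1L]]
  }
  paste(s, collapse = "")
}

random_coding_seq <- function(len) {
  stopifnot(len >= 450)
  utr5 <- max(9L, round(0.15 * len))
  orf_codons <- max(100L, floor((0.7 * len - 6) / 3))
  body <- paste(sample(.synth_codons, orf_codons, replace = TRUE,
                       prob = .synth_codon_w), collapse = "")
  orf <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
  utr3 <- len - utr5 - nchar(orf)
  iid <- function(n) if (n <= 0L) "" else
    paste(sample(names(.synth_nc_prob), n, replace = TRUE,
                 prob = .synth_nc_prob), collapse = "")
  paste0(iid(utr5), orf, iid(utr3))
}

#' Generate transcript sequences with planted coding character
#'
#' Coding transcripts carry an embedded codon-biased ORF covering ~70% of
#' the transcript (always >= 300 nt); non-coding transcripts are drawn from
#' a GC-matched composition with stop codons planted at staggered frames,
#' and are regenerated (bounded retries) until all three built-in
#' predictors score them non-coding against the shipped training corpora,
#' so planted labels are recoverable by construction. Also produces the
#' two hexamer training corpora (drawn from the same two processes).
#'
#' @param config A [synth_config()].
#' @param truth Truth table from [generate_novel_transcripts()].
#' @return List with `seqs` (named vector for every novel transcript),
#'   `training_coding`, `training_noncoding` (named vectors) and the two
#'   trained hexamer models.
#' @export
generate_sequences <- function(config, truth) {
  set.seed(config$seed + 303L)
  n_tr <- config$n_training
  clamp_len <- function(x, lo, hi) round(pmin(hi, pmax(lo, x)))
  tc_len <- clamp_len(stats::rlnorm(n_tr, log(config$mrna_length_mean), 0.35), 450, 6000)
  tn_len <- clamp_len(stats::rlnorm(n_tr, log(config$lnc_length_mean), 0.45), 200, 3000)
  training_coding <- stats::setNames(
    vapply(tc_len, random_coding_seq, character(1)),
    sprintf("TRC%04d", seq_len(n_tr)))
  training_noncoding <- stats::setNames(
    vapply(tn_len, random_noncoding_seq, character(1)),
    sprintf("TRN%04d", seq_len(n_tr)))
  cm <- train_hexamer_model(training_coding)
  ncm <- train_hexamer_model(training_noncoding)

  seqs <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    len <- truth$length[i]
    if (isTRUE(truth$coding[i]) && len >= 450) {
      seqs[i] <- random_coding_seq(len)
    } else {
      for (try in 1:200) {
        s <- random_noncoding_seq(len)
        if (longest_orf(s)$length < 280 &&
            as.numeric(fickett_score(s)) < 0.92 &&
            as.numeric(hexamer_llr(s, cm, ncm)) < -0.01) break
        s <- NULL
      }
      if (is.null(s)) stop("could not generate a non-coding sequence for ",
                           truth$transcript_id[i])
      seqs[i] <- s
    }
  }
  names(seqs) <- truth$transcript_id
  list(seqs = seqs, training_coding = training_coding,
       training_noncoding = training_noncoding,
       coding_model = cm, noncoding_model = ncm)
}

# --------------------------------------------------------------- counts

#' Generate a count matrix with planted differential expression
#'
#' Features are the novel transcripts plus the reference genes. Baseline
#' means are log-normal around `mu`; a `de_fraction` of features gets its
#' second-condition mean multiplied by `2^(+-de_log2fc)` with random sign;
#' planted low-expression lncRNAs get negligible means; counts are NB with
#' dispersion `phi` and per-sample size factors. Planted co-expressed
#' pairs are created afterwards by rewriting the partner gene's counts as
#' a linear function of the lncRNA's realized FPKM (positive or negative
#' slope), so their expression correlation is ~1 in magnitude by
#' construction.
#'
#' @param config A [synth_config()].
#' @param truth Truth table from [generate_novel_transcripts()].
#' @param lengths Named vector of feature lengths for every novel
#'   transcript and reference gene.
#' @param ref_gene_ids Character vector of reference gene ids.
#' @return List with `es` (an [expr_set()]), `de_truth` (`feature_id`,
#'   `status` in up/down/ns/derived, `lfc`), `trans_truth` (`lncrna_id`,
#'   `gene_id`, `sign`) and `qualifying` (per novel transcript: realized
#'   `max_fpkm`).
#' @export
generate_counts <- function(config, truth, lengths, ref_gene_ids) {
  set.seed(config$seed + 404L)
  feat <- c(truth$transcript_id, ref_gene_ids)
  nf <- length(feat)
  n <- config$n_samples
  samples <- c(sprintf("%s_%d", config$groups[1L], seq_len(n)),
               sprintf("%s_%d", config$groups[2L], seq_len(n)))
  groups <- rep(config$groups, each = n)

  mu_f <- stats::rlnorm(nf, meanlog = log(config$mu), sdlog = 1)
  names(mu_f) <- feat
  is_lnc_like <- c(truth$class %in% c("u", "x", "i", "o") & !truth$coding,
                   rep(FALSE, length(ref_gene_ids)))
  low <- is_lnc_like & stats::runif(nf) < config$low_expr_fraction
  mu_f[low] <- 0.02

  de <- !low & stats::runif(nf) < config$de_fraction
  sign <- ifelse(stats::runif(nf) < 0.5, 1, -1)
  lfc <- ifelse(de, sign * config$de_log2fc, 0)
  sf <- stats::runif(2L * n, 0.85, 1.2)

  counts <- matrix(0, nrow = nf, ncol = 2L * n,
                   dimnames = list(feat, samples))
  for (j in seq_len(2L * n)) {
    m <- mu_f * sf[j] * (if (groups[j] == config$groups[2L]) 2^lfc else 1)
    counts[, j] <- if (config$dispersion > 0) {
      stats::rnbinom(nf, mu = m, size = 1 / config$dispersion)
    } else stats::rpois(nf, m)
  }

  de_status <- ifelse(!de, "ns", ifelse(lfc > 0, "up", "down"))
  names(de_status) <- feat

  # plant co-expressed lncRNA-gene pairs on DE, well-expressed lincRNAs
  lib0 <- colSums(counts)
  fpkm0 <- sweep(counts / lengths[feat], 2L, lib0, "/") * 1e9
  cand_lnc <- truth$transcript_id[truth$class == "u" & !truth$coding &
                                    !low[seq_len(nrow(truth))] &
                                    de[seq_len(nrow(truth))] &
                                    truth$length >= 200]
  cand_gene <- ref_gene_ids[!de[match(ref_gene_ids, feat)]]
  n_pairs <- min(config$n_trans_pairs, length(cand_lnc), length(cand_gene))
  trans_truth <- NULL
  if (n_pairs > 0L) {
    lncs <- sample(cand_lnc, n_pairs)
    genes <- sample(cand_gene, n_pairs)
    pair_sign <- ifelse(seq_len(n_pairs) <= ceiling(0.7 * n_pairs), 1, -1)
    for (p in seq_len(n_pairs)) {
      f_l <- fpkm0[lncs[p], ]
      target_fpkm <- if (pair_sign[p] > 0) 2 * f_l else 1.1 * max(f_l) - f_l
      g_counts <- round(target_fpkm * lengths[genes[p]] * lib0 / 1e9)
      counts[genes[p], ] <- pmax(0, g_counts)
      de_status[genes[p]] <- "derived"
    }
    trans_truth <- data.frame(lncrna_id = lncs, gene_id = genes,
                              sign = pair_sign, stringsAsFactors = FALSE)
  }

  es <- expr_set(counts, groups = groups)
  fpkm_final <- fpkm(es, lengths)
  qualifying <- data.frame(
    transcript_id = truth$transcript_id,
    max_fpkm = apply(fpkm_final[truth$transcript_id, , drop = FALSE], 1L, max),
    stringsAsFactors = FALSE
  )
  de_truth <- data.frame(feature_id = feat, status = unname(de_status),
                         lfc = unname(lfc), stringsAsFactors = FALSE)
  list(es = es, de_truth = de_truth, trans_truth = trans_truth,
       qualifying = qualifying)
}

# -------------------------------------------------------------- homology

# documented monotone E-value surrogate: no aligner runs, the conservation
# module only consumes the table, so only ordering matters
synth_evalue <- function(pident, alignment_length) {
  10^pmax(-300, -(pident / 100) * alignment_length / 8)
}

#' Fabricate cross-species homology hit tables with planted RBH pairs
#'
#' For each planted pair a mutated copy of the jasmine lncRNA is placed in
#' one or more species; forward (jasmine -> species) and reverse hit rows
#' are fabricated directly from the known identity and coverage, with
#' E-values from a documented monotone surrogate formula. One-way-only
#' conserved queries get a forward hit without a reverse best hit; decoy
#' rows fail either the E-value or the coverage filter.
#'
#' @param config A [synth_config()].
#' @param lnc_seqs Named vector: sequences of the plantable lncRNAs.
#' @return List with per-species elements `forward` / `reverse` (hit
#'   tables), `species_seqs` (named vectors), and truth tables
#'   `conserved_truth` (`query_id`, `species`) and `rbh_truth`
#'   (`query_id`, `species`, `subject_id`).
#' @export
generate_homology <- function(config, lnc_seqs) {
  set.seed(config$seed + 505L)
  species <- c("A_thaliana", "S_lycopersicum", "C_quinoa", "C_sativus",
               "M_esculenta", sprintf("species%02d", seq_len(max(0, config$n_species - 5L))))
  species <- species[seq_len(config$n_species)]
  ids <- names(lnc_seqs)
  n_planted <- min(config$n_planted_homologs, length(ids))
  planted <- if (n_planted > 0L) sample(ids, n_planted) else character(0)
  rest <- setdiff(ids, planted)
  n_oneway <- min(config$n_oneway_homologs, length(rest))
  oneway <- if (n_oneway > 0L) sample(rest, n_oneway) else character(0)
  decoy_pool <- setdiff(rest, oneway)

  fwd <- stats::setNames(vector("list", length(species)), species)
  rev <- fwd
  spseq <- fwd
  conserved <- list(); rbh <- list()
  hit_row <- function(q, s, pident, alen, evalue, bits) {
    data.frame(query_id = q, subject_id = s, percent_identity = pident,
               alignment_length = alen, mismatches = round(alen * (1 - pident / 100)),
               gap_opens = 0L, qstart = 1L, qend = alen, sstart = 1L, send = alen,
               evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
  }
  mutate_seq <- function(s, rate) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    list(seq = paste(b, collapse = ""), n_sub = length(hit))
  }

  hcount <- 0L
  for (q in c(planted, oneway)) {
    n_sp <- sample.int(min(3L, length(species)), 1L)
    sps <- sample(species, n_sp)
    for (sp in sps) {
      hcount <- hcount + 1L
      m <- mutate_seq(lnc_seqs[[q]], config$mutation_rate)
      sid <- sprintf("%s_h%04d", sp, hcount)
      spseq[[sp]][sid] <- m$seq
      len <- nchar(lnc_seqs[[q]])
      alen <- max(round(len * stats::runif(1L, 0.6, 1.0)), round(0.35 * len))
      pident <- round(100 * (1 - m$n_sub / len), 2)
      ev <- synth_evalue(pident, alen)
      bits <- round(1.85 * alen * pident / 100)
      fwd[[sp]] <- rbind(fwd[[sp]], hit_row(q, sid, pident, alen, ev, bits))
      conserved[[length(conserved) + 1L]] <-
        data.frame(query_id = q, species = sp, stringsAsFactors = FALSE)
      if (q %in% planted) {
        rev[[sp]] <- rbind(rev[[sp]], hit_row(sid, q, pident, alen, ev, bits))
        rbh[[length(rbh) + 1L]] <- data.frame(
          query_id = q, species = sp, subject_id = sid, stringsAsFactors = FALSE)
        # a weaker secondary subject to exercise best-hit selection
        if (stats::runif(1L) < 0.3) {
          sid2 <- sprintf("%s_w%04d", sp, hcount)
          spseq[[sp]][sid2] <- random_noncoding_seq(len)
          fwd[[sp]] <- rbind(fwd[[sp]],
            hit_row(q, sid2, pident - 5, round(alen * 0.8),
                    synth_evalue(pident - 5, round(alen * 0.8)),
                    round(0.7 * bits)))
        }
      }
    }
  }

  # decoys: fail E-value or coverage
  n_dec <- min(config$n_decoy_hits, length(decoy_pool) * length(species))
  if (n_dec > 0L && length(decoy_pool)) {
    dq <- sample(decoy_pool, n_dec, replace = TRUE)
    dsp <- sample(species, n_dec, replace = TRUE)
    for (d in seq_len(n_dec)) {
      hcount <- hcount + 1L
      sid <- sprintf("%s_d%04d", dsp[d], hcount)
      len <- nchar(lnc_seqs[[dq[d]]])
      spseq[[dsp[d]]][sid] <- random_noncoding_seq(max(60L, round(0.3 * len)))
      if (stats::runif(1L) < 0.5) {
        alen <- round(0.5 * len)               # fails the E-value filter
        fwd[[dsp[d]]] <- rbind(fwd[[dsp[d]]],
          hit_row(dq[d], sid, 72, alen, 1e-6, round(alen)))
      } else {                                  # fails the coverage filter
        alen <- max(20L, round(0.15 * len))
        fwd[[dsp[d]]] <- rbind(fwd[[dsp[d]]],
          hit_row(dq[d], sid, 92, alen, 1e-30, round(1.8 * alen)))
      }
    }
  }

  for (sp in species) {
    if (is.null(fwd[[sp]])) fwd[[sp]] <- empty_hit_table()[, 1:12]
    if (is.null(rev[[sp]])) rev[[sp]] <- empty_hit_table()[, 1:12]
    if (is.null(spseq[[sp]])) spseq[[sp]] <- character(0)
  }
  list(
    forward = fwd, reverse = rev, species_seqs = spseq,
    conserved_truth = if (length(conserved)) unique(do.call(rbind, conserved))
      else data.frame(query_id = character(0), species = character(0)),
    rbh_truth = if (length(rbh)) do.call(rbind, rbh)
      else data.frame(query_id = character(0), species = character(0),
                      subject_id = character(0))
  )
}

# --------------------------------------------------------------- bundle

#' Generate the complete synthetic input bundle
#'
#' Runs every generator stage under one seed and writes all pipeline
#' inputs plus the ground-truth tables into `dir`:
#' `reference.gtf`, `chrom_sizes.tsv`, `novel.gtf`, `novel.fa`,
#' `training_coding.fa`, `training_noncoding.fa`, `counts.tsv`,
#' `samples.tsv`, `term_map.tsv`, `homology/<species>_{forward,reverse}.tsv`
#' and `homology/<species>.fa`, and `truth/{classes,de,trans_pairs,
#' conserved,rbh,cis_pairs}.tsv`.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly; side effect: files written.
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "homology"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  ann <- generate_annotation(config)
  write_gtf(ann$exons, file.path(dir, "reference.gtf"))
  write_tsv(data.frame(chrom = names(ann$chrom_sizes),
                       size = unname(ann$chrom_sizes)),
            file.path(dir, "chrom_sizes.tsv"))

  nov <- generate_novel_transcripts(config, ann)
  write_gtf(nov$exons, file.path(dir, "novel.gtf"))

  sq <- generate_sequences(config, nov$truth)
  write_fasta(sq$seqs, file.path(dir, "novel.fa"))
  write_fasta(sq$training_coding, file.path(dir, "training_coding.fa"))
  write_fasta(sq$training_noncoding, file.path(dir, "training_noncoding.fa"))

  ref_st <- transcript_stats(ann$exons)
  gene_len <- tapply(ref_st$length, ref_st$gene_id, max)
  lengths <- c(stats::setNames(nov$truth$length, nov$truth$transcript_id),
               stats::setNames(as.numeric(gene_len), names(gene_len)))
  cnt <- generate_counts(config, nov$truth, lengths, sort(unique(ref_st$gene_id)))
  write_counts(cnt$es, file.path(dir, "counts.tsv"),
               file.path(dir, "samples.tsv"))

  # term map over reference genes
  set.seed(config$seed + 606L)
  gene_ids <- sort(unique(ref_st$gene_id))
  term_map <- do.call(rbind, lapply(seq_len(config$n_terms), function(t) {
    size <- sample(5:30, 1L)
    data.frame(term_id = sprintf("TERM%03d", t),
               term_name = sprintf("synthetic process %03d", t),
               gene_id = sample(gene_ids, min(size, length(gene_ids))),
               stringsAsFactors = FALSE)
  }))
  write_tsv(term_map, file.path(dir, "term_map.tsv"))

  # homology over qualifying non-coding novel transcripts
  qual <- merge(nov$truth, cnt$qualifying, by = "transcript_id")
  qual_ids <- qual$transcript_id[!qual$coding & qual$class %in% c("u", "x", "i", "o") &
                                   qual$length >= 200 & qual$max_fpkm >= 0.5]
  hom <- generate_homology(config, sq$seqs[sort(qual_ids)])
  for (sp in names(hom$forward)) {
    utils::write.table(hom$forward[[sp]], file.path(dir, "homology",
                                                    paste0(sp, "_forward.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(hom$reverse[[sp]], file.path(dir, "homology",
                                                    paste0(sp, "_reverse.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    sps <- hom$species_seqs[[sp]]
    if (length(sps) == 0L) sps <- c(placeholder = "N")  # keep a readable file
    write_fasta(sps, file.path(dir, "homology", paste0(sp, ".fa")))
  }

  # cis truth: brute-force gaps between qualifying lncRNAs and gene spans
  nov_st <- transcript_stats(nov$exons)
  gene_span <- data.frame(
    gene_id = ref_st$gene_id, chrom = ref_st$chrom,
    start = as.numeric(tapply(ref_st$start, ref_st$gene_id, min)[ref_st$gene_id]),
    end = as.numeric(tapply(ref_st$end, ref_st$gene_id, max)[ref_st$gene_id]),
    stringsAsFactors = FALSE)
  gene_span <- gene_span[!duplicated(gene_span$gene_id), ]
  cis_rows <- list()
  for (tid in qual_ids) {
    l <- nov_st[nov_st$transcript_id == tid, ]
    same <- gene_span[gene_span$chrom == l$chrom, , drop = FALSE]
    gap <- pmax(0, pmax(l$start, same$start) - pmin(l$end, same$end))
    keep <- gap <= 100000
    if (any(keep)) {
      cis_rows[[tid]] <- data.frame(lncrna_id = tid, gene_id = same$gene_id[keep],
                                    distance = gap[keep], stringsAsFactors = FALSE)
    }
  }
  cis_truth <- if (length(cis_rows)) do.call(rbind, cis_rows) else
    data.frame(lncrna_id = character(0), gene_id = character(0),
               distance = numeric(0))
  rownames(cis_truth) <- NULL

  write_tsv(cbind(nov$truth, max_fpkm = cnt$qualifying$max_fpkm[
    match(nov$truth$transcript_id, cnt$qualifying$transcript_id)]),
    file.path(dir, "truth", "classes.tsv"))
  write_tsv(cnt$de_truth, file.path(dir, "truth", "de.tsv"))
  if (!is.null(cnt$trans_truth)) {
    write_tsv(cnt$trans_truth, file.path(dir, "truth", "trans_pairs.tsv"))
  }
  write_tsv(hom$conserved_truth, file.path(dir, "truth", "conserved.tsv"))
  write_tsv(hom$rbh_truth, file.path(dir, "truth", "rbh.tsv"))
  write_tsv(cis_truth, file.path(dir, "truth", "cis_pairs.tsv"))
  invisible(dir)
}
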