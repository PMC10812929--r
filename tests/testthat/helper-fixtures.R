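# Shared fixtures: a cached default synthetic bundle + pipeline run (several
# files assert against the same run), brute-force oracles, and small builders.

.fixture_env <- new.env(parent = emptyenv())

default_bundle_dir <- function() {
  if (is.null(.fixture_env$bundle)) {
    dir <- file.path(tempdir(), "lncid-default-bundle")
    generate_bundle(synth_config(seed = 1), dir)
    .fixture_env$bundle <- dir
  }
  .fixture_env$bundle
}

default_run <- function() {
  if (is.null(.fixture_env$run)) {
    out <- file.path(tempdir(), "lncid-default-out")
    .fixture_env$run <- run_pipeline(run_config(default_bundle_dir(), out))
    .fixture_env$run_dir <- out
  }
  .fixture_env$run
}

read_truth <- function(name) {
  utils::read.delim(file.path(default_bundle_dir(), "truth", name),
                    stringsAsFactors = FALSE)
}

# expression set builder with equal library sizes
make_es <- function(counts, n_per_group = ncol(counts) / 2) {
  colnames(counts) <- c(sprintf("A_%d", seq_len(n_per_group)),
                        sprintf("B_%d", seq_len(ncol(counts) - n_per_group)))
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("f%04d", seq_len(nrow(counts)))
  }
  expr_set(counts,
           groups = rep(c("A", "B"), c(n_per_group, ncol(counts) - n_per_group)),
           library_sizes = rep(1e6, ncol(counts)))
}

# single-transcript exon table builder
tx <- function(id, chrom, strand, starts, ends, gene = paste0(id, "_g")) {
  data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
             strand = strand, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# ---- brute-force positional classifier (independent of the indexed path)
brute_force_classify <- function(query_exons, ref_exons) {
  qst <- transcript_stats(query_exons)
  rst <- transcript_stats(ref_exons)
  rex <- split(ref_exons, ref_exons$transcript_id)
  out <- character(nrow(qst))
  for (i in seq_len(nrow(qst))) {
    qx <- query_exons[query_exons$transcript_id == qst$transcript_id[i], ]
    code <- "u"
    same_o <- FALSE; opp_x <- FALSE; same_i <- FALSE; same_eq <- FALSE
    for (j in seq_len(nrow(rst))) {
      if (rst$chrom[j] != qst$chrom[i]) next
      rx <- rex[[rst$transcript_id[j]]]
      rx <- rx[order(rx$start), ]
      ov <- exonic_overlap_bp(qx, rx)
      if (rst$strand[j] == qst$strand[i]) {
        if (nrow(rx) == nrow(qx) && all(sort(rx$start) == sort(qx$start)) &&
            all(sort(rx$end) == sort(qx$end))) same_eq <- TRUE
        if (ov > 0) same_o <- TRUE
        if (nrow(rx) >= 2) {
          is_ <- rx$end[-nrow(rx)]; ie_ <- rx$start[-1]
          if (any(qst$start[i] >= is_ & qst$end[i] <= ie_)) same_i <- TRUE
        }
      } else if (ov > 0) opp_x <- TRUE
    }
    out[i] <- if (same_eq) "=" else if (same_o) "o" else if (same_i) "i"
      else if (opp_x) "x" else "u"
  }
  stats::setNames(out, qst$transcript_id)
}

# ---- brute-force ORF enumeration over all (ATG, stop) pairs in 3 frames
brute_force_orf_length <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  for (f in 0:2) {
    starts <- seq.int(f + 1L, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    for (a in which(codons == "ATG")) {
      stop_at <- which(codons %in% c("TAA", "TAG", "TGA"))
      stop_at <- stop_at[stop_at > a]
      len <- if (length(stop_at)) (min(stop_at) - a + 1L) * 3L
             else (length(codons) - a + 1L) * 3L
      best <- max(best, len)
    }
  }
  best
}

# ---- first-order Markov resample preserving local dinucleotide composition
markov_shuffle <- function(s) {
  b <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(b)
  tr <- table(factor(b[-n], levels = c("A", "C", "G", "T")),
              factor(b[-1L], levels = c("A", "C", "G", "T")))
  out <- character(n)
  out[1L] <- b[1L]
  for (i in 2:n) {
    row <- tr[out[i - 1L], ]
    out[i] <- if (sum(row) == 0) sample(c("A", "C", "G", "T"), 1L) else
      sample(colnames(tr), 1L, prob = row)
  }
  paste(out, collapse = "")
}

# ---- planted co-expression experiment: 20 linear pairs among 500 decoys
coexpression_experiment <- function(seed = 9, n_samples = 6, n_decoys = 500,
                                    n_planted = 20) {
  set.seed(seed)
  gene_expr <- matrix(stats::rnbinom(n_decoys * n_samples, mu = 200, size = 10),
                      n_decoys, n_samples,
                      dimnames = list(sprintf("G%03d", seq_len(n_decoys)),
                                      sprintf("s%d", seq_len(n_samples))))
  lnc_expr <- matrix(stats::rnbinom(n_planted * n_samples, mu = 200, size = 10),
                     n_planted, n_samples,
                     dimnames = list(sprintf("L%02d", seq_len(n_planted)),
                                     sprintf("s%d", seq_len(n_samples))))
  sign <- rep(c(1, -1), length.out = n_planted)
  planted_gene <- sprintf("G%03d", seq_len(n_planted))
  for (i in seq_len(n_planted)) {
    gene_expr[planted_gene[i], ] <- if (sign[i] > 0) 2 * lnc_expr[i, ] else
      round(1.1 * max(lnc_expr[i, ]) - lnc_expr[i, ])
  }
  list(lnc_expr = lnc_expr, gene_expr = gene_expr,
       planted = data.frame(lncrna_id = rownames(lnc_expr),
                            gene_id = planted_gene, stringsAsFactors = FALSE))
}
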