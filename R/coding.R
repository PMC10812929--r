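#' Longest open reading frame on the sense strand
#'
#' Scans the three sense-strand frames (transcripts from stranded RNA-seq
#' are already oriented) for the longest `ATG`..`TAA`/`TAG`/`TGA` span,
#' inclusive of the stop codon. If an `ATG` has no downstream in-frame
#' stop, the open-ended span to the last complete codon is reported with
#' `has_stop = FALSE`. Ties are broken by the smaller start offset.
#'
#' @param seq Nucleotide string over A/C/G/T/N (case-insensitive).
#' @param frames Frames to scan; default sense-strand `0:2`. Pass the
#'   reverse complement yourself for a 6-frame scan of unstranded input.
#' @return List with `start` (0-based nt offset, `NA` if no ORF), `length`
#'   (nt, 0 if no ORF), `frame` and `has_stop`.
#' @export
longest_orf <- function(seq, frames = 0:2) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- list(start = NA_integer_, length = 0L, frame = NA_integer_,
               has_stop = FALSE)
  if (n < 3L) return(best)
  for (f in frames) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (a in atg) {
      nxt <- stop_idx[stop_idx > a]
      if (length(nxt)) {
        len <- (nxt[1L] - a + 1L) * 3L
        has_stop <- TRUE
      } else {
        len <- (length(codons) - a + 1L) * 3L
        has_stop <- FALSE
      }
      start0 <- f + (a - 1L) * 3L
      if (len > best$length ||
          (len == best$length && !is.na(best$start) && start0 < best$start)) {
        best <- list(start = start0, length = len, frame = f, has_stop = has_stop)
      }
    }
  }
  best
}

#' Fickett TESTCODE score
#'
#' The classic position/composition statistic: for each base, the
#' positional asymmetry `max(n1,n2,n3)/(min(n1,n2,n3)+1)` over the three
#' codon positions and the overall content fraction are mapped through the
#' published lookup tables and combined as the published weighted sum.
#' Scores above ~0.95 conventionally indicate "probably coding", below
#' ~0.74 "probably non-coding".
#'
#' @param seq Nucleotide string (A/C/G/T/N). Sequences under 200 nt are
#'   scored but flagged low-confidence; sequences with > 10% N are flagged.
#' @return Numeric score with attributes `low_confidence` and `high_n`
#'   (logical flags).
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) {
    return(structure(0, low_confidence = TRUE, high_n = FALSE))
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  high_n <- mean(bases == "N") > 0.10
  pos <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- tabulate(pos[bases == b] + 1L, nbins = 3L)
    asym <- max(counts) / (min(counts) + 1)
    bin <- .fickett_bin(asym, .fickett_position_para)
    score <- score + .fickett_position_prob[[b]][bin] * .fickett_position_weight[[b]]
    content <- sum(counts) / n
    bin <- .fickett_bin(content, .fickett_content_para)
    score <- score + .fickett_content_prob[[b]][bin] * .fickett_content_weight[[b]]
  }
  structure(score, low_confidence = n < 200L, high_n = high_n)
}

#' Train a hexamer frequency model
#'
#' Counts all overlapping hexamers (step 1) across a corpus and converts
#' them to smoothed probabilities over the 4096 possible hexamers.
#' Hexamers containing N are ignored.
#'
#' @param seqs Character vector of sequences (>= 1).
#' @param pseudocount Additive smoothing constant (> 0).
#' @return Named numeric vector of 4096 probabilities summing to 1, class
#'   `hexamer_model`.
#' @export
train_hexamer_model <- function(seqs, pseudocount = 1) {
  if (length(seqs) == 0L) stop("empty training corpus")
  stopifnot(pseudocount > 0)
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  counts <- colSums(Biostrings::oligonucleotideFrequency(ss, width = 6L, step = 1L))
  probs <- (counts + pseudocount) / (sum(counts) + pseudocount * length(counts))
  structure(probs, class = "hexamer_model")
}

#' Hexamer log-likelihood ratio score
#'
#' Mean, over in-frame-style step-3 hexamer windows, of
#' `log(P_coding / P_noncoding)`. Positive scores indicate hexamer usage
#' closer to the coding corpus. Sequences shorter than 6 nt score 0 with a
#' `too_short` flag.
#'
#' @param seq Nucleotide string.
#' @param coding_model,noncoding_model [train_hexamer_model()] objects.
#' @return Numeric score with attribute `too_short`.
#' @export
hexamer_llr <- function(seq, coding_model, noncoding_model) {
  stopifnot(inherits(coding_model, "hexamer_model"),
            inherits(noncoding_model, "hexamer_model"))
  seq <- toupper(seq)
  if (nchar(seq) < 6L) {
    return(structure(0, too_short = TRUE))
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq), width = 6L, step = 3L)
  n <- sum(counts)
  if (n == 0L) {
    return(structure(0, too_short = TRUE))
  }
  llr <- log(unclass(coding_model)) - log(unclass(noncoding_model))
  structure(sum(counts * llr) / n, too_short = FALSE)
}

#' Default thresholds for the per-predictor coding calls
#'
#' A predictor calls "coding" when: ORF length >= `min_orf` nt; Fickett
#' score >= `min_fickett` (the conventional TESTCODE "probably coding"
#' region); hexamer log-likelihood ratio > `min_hexamer`.
#'
#' @param min_orf,min_fickett,min_hexamer Thresholds.
#' @return Named list of thresholds.
#' @export
coding_thresholds <- function(min_orf = 300, min_fickett = 0.95, min_hexamer = 0) {
  list(min_orf = min_orf, min_fickett = min_fickett, min_hexamer = min_hexamer)
}

#' Score coding potential of transcript sequences
#'
#' Runs the three built-in predictors over every sequence.
#'
#' @param seqs Named character vector of transcript sequences.
#' @param coding_model,noncoding_model Trained [train_hexamer_model()]s.
#' @return `data.frame` with `transcript_id`, `orf_length`, `fickett`,
#'   `hexamer_llr`.
#' @export
score_coding_potential <- function(seqs, coding_model, noncoding_model) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  data.frame(
    transcript_id = names(seqs),
    orf_length = vapply(seqs, function(s) as.numeric(longest_orf(s)$length), numeric(1)),
    fickett = vapply(seqs, function(s) as.numeric(fickett_score(s)), numeric(1)),
    hexamer_llr = vapply(seqs, function(s)
      as.numeric(hexamer_llr(s, coding_model, noncoding_model)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Intersection vote over the three coding predictors
#'
#' A transcript is non-coding only when all three predictors agree it is
#' non-coding (the set-intersection rule: the lncRNA set is the overlap of
#' the per-predictor non-coding sets).
#'
#' @param scores `data.frame` from [score_coding_potential()] (columns
#'   `transcript_id`, `orf_length`, `fickett`, `hexamer_llr`).
#' @param thresholds [coding_thresholds()].
#' @return `scores` with added logical columns `call_orf`, `call_fickett`,
#'   `call_hexamer` (TRUE = coding) and `is_noncoding`.
#' @export
ensemble_noncoding_vote <- function(scores, thresholds = coding_thresholds()) {
  needed <- c("transcript_id", "orf_length", "fickett", "hexamer_llr")
  if (!all(needed %in% names(scores))) {
    stop("missing predictor column(s): ",
         paste(setdiff(needed, names(scores)), collapse = ", "))
  }
  scores$call_orf <- scores$orf_length >= thresholds$min_orf
  scores$call_fickett <- scores$fickett >= thresholds$min_fickett
  scores$call_hexamer <- scores$hexamer_llr > thresholds$min_hexamer
  scores$is_noncoding <- !(scores$call_orf | scores$call_fickett | scores$call_hexamer)
  scores
}

#' Ingest external coding-potential predictions
#'
#' Instead of the built-in predictors, per-transcript calls can come from
#' the tabular outputs of external tools: a CPC2-style table (id column +
#' `label` column with `coding`/`noncoding`), a CNCI-style table (id
#' column + `score` column, negative = non-coding), and a Pfam-style hit
#' table (columns `transcript_id` and `hit`; any non-empty, non-`-` hit
#' means coding). Transcripts absent from any table are excluded with a
#' warning.
#'
#' @param cpc2,cnci,pfam `data.frame`s or TSV paths.
#' @return `data.frame` with `transcript_id`, logical `call_cpc2`,
#'   `call_cnci`, `call_pfam` (TRUE = coding) and `is_noncoding`.
#' @export
ingest_external_predictions <- function(cpc2, cnci, pfam) {
  as_table <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      utils::read.delim(x, stringsAsFactors = FALSE)
    } else as.data.frame(x)
  }
  cpc2 <- as_table(cpc2); cnci <- as_table(cnci); pfam <- as_table(pfam)
  if (!"label" %in% names(cpc2)) stop("CPC2 table needs a 'label' column")
  bad <- !cpc2$label %in% c("coding", "noncoding")
  if (any(bad)) {
    stop("unparseable CPC2 label for transcript(s): ",
         paste(cpc2[[1L]][bad], collapse = ", "))
  }
  if (!"score" %in% names(cnci)) stop("CNCI table needs a 'score' column")
  if (!all(c("transcript_id", "hit") %in% names(pfam))) {
    stop("Pfam table needs 'transcript_id' and 'hit' columns")
  }
  pfam_coding <- tapply(
    !is.na(pfam$hit) & nzchar(pfam$hit) & pfam$hit != "-",
    pfam$transcript_id, any)
  ids <- Reduce(intersect, list(as.character(cpc2[[1L]]),
                                as.character(cnci[[1L]]),
                                names(pfam_coding)))
  all_ids <- unique(c(as.character(cpc2[[1L]]), as.character(cnci[[1L]]),
                      names(pfam_coding)))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped)) {
    warning(length(dropped), " transcript(s) absent from at least one ",
            "predictor table excluded: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  out <- data.frame(
    transcript_id = ids,
    call_cpc2 = cpc2$label[match(ids, cpc2[[1L]])] == "coding",
    call_cnci = cnci$score[match(ids, cnci[[1L]])] >= 0,
    call_pfam = as.logical(pfam_coding[ids]),
    stringsAsFactors = FALSE
  )
  out$is_noncoding <- !(out$call_cpc2 | out$call_cnci | out$call_pfam)
  rownames(out) <- NULL
  out
}
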