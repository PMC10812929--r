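#' Total exonic overlap between two transcripts
#'
#' Sum over all exon pairs of intersection lengths, in bp. Transcripts on
#' different chromosomes overlap by 0 bp; the result is symmetric in its
#' arguments.
#'
#' @param query,subject Exon tables of a single transcript each (rows of a
#'   [read_gtf()] table), or any data.frame with `chrom`, `start`, `end`.
#' @return Overlap in bp (numeric scalar).
#' @export
exonic_overlap_bp <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) return(0)
  if (query$chrom[1L] != subject$chrom[1L]) return(0)
  total <- 0
  for (i in seq_len(nrow(query))) {
    ov <- pmin(query$end[i], subject$end) - pmax(query$start[i], subject$start)
    total <- total + sum(pmax(0, ov))
  }
  total
}

#' Build an interval index over a reference annotation
#'
#' Precomputes, per reference transcript, the exon chain, intron set and
#' locus span, backed by [GenomicRanges::GRanges] so that class-code
#' assignment queries only the transcripts whose span overlaps the probe.
#'
#' @param ref_exons Reference exon table ([read_gtf()]).
#' @return An object of class `ref_index`.
#' @export
build_reference_index <- function(ref_exons) {
  check_exon_table(ref_exons)
  ref_exons <- canonical_exon_order(ref_exons)
  st <- transcript_stats(ref_exons)
  ex_by_tx <- split(ref_exons[c("start", "end")],
                    factor(ref_exons$transcript_id, levels = st$transcript_id))
  spans <- GenomicRanges::GRanges(
    seqnames = st$chrom,
    ranges = IRanges::IRanges(start = st$start + 1L, end = st$end)
  )
  structure(
    list(stats = st, exons_by_tx = ex_by_tx, spans = spans),
    class = "ref_index"
  )
}

#' Assign positional class codes relative to a reference annotation
#'
#' Each stranded query transcript gets exactly one code describing its
#' position relative to the reference annotation:
#' \describe{
#'   \item{`=`}{identical exon chain as a same-strand reference transcript
#'     (identical exon coordinates; strict, no slack)}
#'   \item{`o`}{same-strand exonic overlap (sense)}
#'   \item{`i`}{entirely contained in an intron of a same-strand reference
#'     transcript (intronic)}
#'   \item{`x`}{opposite-strand exonic overlap (antisense)}
#'   \item{`u`}{none of the above (intergenic)}
#' }
#' Precedence is `=` > `o` > `i` > `x` > `u`: a transcript overlapping
#' exons on both strands is called sense, not antisense. Queries contained
#' in an opposite-strand gene span without exonic overlap fall through to
#' `u` and are flagged in the `note` column. Unstranded (`.`) queries are
#' excluded with a warning.
#'
#' @param query_exons Exon table of the transcripts to classify.
#' @param ref_index A [build_reference_index()] object.
#' @return `data.frame` with columns `transcript_id`, `code`,
#'   `subject_gene_id` (empty for `u`) and `note`.
#' @export
classify_transcripts <- function(query_exons, ref_index) {
  check_exon_table(query_exons)
  stopifnot(inherits(ref_index, "ref_index"))
  qst <- transcript_stats(query_exons)
  unstranded <- qst$strand == "."
  if (any(unstranded)) {
    warning(sum(unstranded), " unstranded quer",
            if (sum(unstranded) == 1L) "y" else "ies",
            " rejected from classification: ",
            paste(utils::head(qst$transcript_id[unstranded], 5L), collapse = ", "))
    qst <- qst[!unstranded, , drop = FALSE]
  }
  q_exons_by_tx <- split(query_exons[c("start", "end")],
                         factor(query_exons$transcript_id, levels = qst$transcript_id))
  if (nrow(qst) == 0L) {
    return(data.frame(transcript_id = character(0), code = character(0),
                      subject_gene_id = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  }
  q_spans <- GenomicRanges::GRanges(
    seqnames = qst$chrom,
    ranges = IRanges::IRanges(start = qst$start + 1L, end = qst$end)
  )
  ov <- GenomicRanges::findOverlaps(q_spans, ref_index$spans)
  cand <- split(S4Vectors::subjectHits(ov), factor(S4Vectors::queryHits(ov),
                                                   levels = seq_len(nrow(qst))))
  code <- character(nrow(qst))
  subj <- character(nrow(qst))
  note <- character(nrow(qst))
  rst <- ref_index$stats
  for (k in seq_len(nrow(qst))) {
    res <- classify_one(
      qx = q_exons_by_tx[[k]],
      q_strand = qst$strand[k],
      q_span = c(qst$start[k], qst$end[k]),
      cand_idx = cand[[k]],
      rst = rst,
      ref_exons_by_tx = ref_index$exons_by_tx
    )
    code[k] <- res$code
    subj[k] <- res$subject_gene_id
    note[k] <- res$note
  }
  data.frame(transcript_id = qst$transcript_id, code = code,
             subject_gene_id = subj, note = note, stringsAsFactors = FALSE)
}

# decision procedure for one query against its span-overlapping candidates
classify_one <- function(qx, q_strand, q_span, cand_idx, rst, ref_exons_by_tx) {
  if (length(cand_idx) == 0L) {
    return(list(code = "u", subject_gene_id = "", note = ""))
  }
  cand_idx <- cand_idx[order(rst$gene_id[cand_idx], rst$transcript_id[cand_idx])]
  same <- cand_idx[rst$strand[cand_idx] == q_strand]
  opp <- cand_idx[rst$strand[cand_idx] != q_strand]
  # (a) '=': identical exon chain, same strand
  for (j in same) {
    rx <- ref_exons_by_tx[[j]]
    if (nrow(rx) == nrow(qx) &&
        all(rx$start == qx$start) && all(rx$end == qx$end)) {
      return(list(code = "=", subject_gene_id = rst$gene_id[j], note = ""))
    }
  }
  # (b) 'o': same-strand exonic overlap
  for (j in same) {
    if (pair_overlap_bp(qx, ref_exons_by_tx[[j]]) > 0) {
      return(list(code = "o", subject_gene_id = rst$gene_id[j], note = ""))
    }
  }
  # (c) 'i': fully inside an intron of a same-strand reference transcript
  for (j in same) {
    rx <- ref_exons_by_tx[[j]]
    if (nrow(rx) >= 2L) {
      intron_start <- rx$end[-nrow(rx)]
      intron_end <- rx$start[-1L]
      if (any(q_span[1L] >= intron_start & q_span[2L] <= intron_end)) {
        return(list(code = "i", subject_gene_id = rst$gene_id[j], note = ""))
      }
    }
  }
  # (d) 'x': opposite-strand exonic overlap
  for (j in opp) {
    if (pair_overlap_bp(qx, ref_exons_by_tx[[j]]) > 0) {
      return(list(code = "x", subject_gene_id = rst$gene_id[j], note = ""))
    }
  }
  # (e) 'u'; note span containment in an opposite-strand gene
  contained <- vapply(opp, function(j) {
    q_span[1L] >= rst$start[j] && q_span[2L] <= rst$end[j]
  }, logical(1))
  note <- if (length(opp) && any(contained)) {
    "contained in opposite-strand gene span without exonic overlap"
  } else ""
  list(code = "u", subject_gene_id = "", note = note)
}

# overlap between two start/end-only exon frames (same chromosome implied)
pair_overlap_bp <- function(qx, sx) {
  total <- 0
  for (i in seq_len(nrow(qx))) {
    ov <- pmin(qx$end[i], sx$end) - pmax(qx$start[i], sx$start)
    total <- total + sum(pmax(0, ov))
  }
  total
}

#' Feature density along chromosomes
#'
#' Counts each feature once, in the bin containing its start position.
#' Features on chromosomes absent from `chrom_sizes` are excluded with a
#' warning.
#'
#' @param features data.frame with `chrom` and `start` (0-based).
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (> 0).
#' @return `data.frame` with `chrom`, `bin_start`, `count`, covering every
#'   bin of every chromosome in `chrom_sizes`.
#' @export
chromosome_density <- function(features, chrom_sizes, bin_size) {
  stopifnot(bin_size > 0, is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  unknown <- !(features$chrom %in% names(chrom_sizes))
  if (any(unknown)) {
    warning(sum(unknown), " feature(s) on unknown chromosome(s) excluded")
    features <- features[!unknown, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n_bins <- max(1L, ceiling(chrom_sizes[[ch]] / bin_size))
    starts <- (seq_len(n_bins) - 1L) * bin_size
    f <- features[features$chrom == ch, , drop = FALSE]
    bins <- pmin(floor(f$start / bin_size), n_bins - 1L)
    counts <- tabulate(bins + 1L, nbins = n_bins)
    data.frame(chrom = ch, bin_start = starts, count = counts,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
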