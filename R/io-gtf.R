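#' Read transcript models from a GTF file
#'
#' Parses exon features of a 9-column GTF file into an exon table, the
#' internal transcript-model representation used throughout the package.
#' External GTF coordinates are 1-based inclusive; internally all intervals
#' are 0-based half-open, so a GTF exon `start=1, end=100` becomes the
#' interval `[0, 100)` of length 100. The conversion happens only here and
#' in [write_gtf()], so every other function can use plain interval
#' arithmetic.
#'
#' @param path Path to a GTF file. Lines whose feature type is not `exon`
#'   are ignored; exon lines must carry `transcript_id` and `gene_id`
#'   attributes.
#' @return A `data.frame` with one row per exon and columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand` (`+`, `-` or `.`),
#'   `start` (0-based inclusive) and `end` (exclusive). Exons are sorted by
#'   start within each transcript and transcripts by (chrom, span start,
#'   transcript_id); this canonical ordering is what [write_gtf()] emits,
#'   so read/write round trips are exact.
#' @seealso [write_gtf()], [transcript_stats()]
#' @export
read_gtf <- function(path) {
  stopifnot(file.exists(path))
  validate_gtf_lines(path)
  raw <- readLines(path)
  if (!any(nzchar(raw) & !startsWith(raw, "#"))) {
    return(empty_exon_table())
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) {
    return(empty_exon_table())
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id)) {
    stop("GTF exon records without a transcript_id attribute in ", path)
  }
  if (is.null(mc$gene_id) || anyNA(mc$gene_id)) {
    stop("GTF exon records without a gene_id attribute in ", path)
  }
  exons <- data.frame(
    transcript_id = as.character(mc$transcript_id),
    gene_id       = as.character(mc$gene_id),
    chrom         = as.character(GenomicRanges::seqnames(gr)),
    strand        = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    start         = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end           = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  canonical_exon_order(exons)
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exons are written as
#' 1-based inclusive GTF exon records, so `read_gtf(write_gtf(x))` is the
#' identity on canonically ordered exon tables.
#'
#' @param exons An exon table as returned by [read_gtf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  check_exon_table(exons)
  exons <- canonical_exon_order(exons)
  if (nrow(exons) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = chartr(".", "*", exons$strand)
  )
  S4Vectors::mcols(gr)$source <- "lncid"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id
  S4Vectors::mcols(gr)$transcript_id <- exons$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# Field-level validation with line numbers; rtracklayer's parser reports
# failures but not which record is at fault.
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L) {
      stop("GTF parse error at line ", i, ": expected >= 9 tab-separated fields, got ",
           length(fields))
    }
    start <- suppressWarnings(as.numeric(fields[[4]]))
    end <- suppressWarnings(as.numeric(fields[[5]]))
    if (is.na(start) || is.na(end)) {
      stop("GTF parse error at line ", i, ": non-numeric coordinates")
    }
    if (end < start) {
      stop("GTF parse error at line ", i, ": end < start")
    }
    if (!fields[[7]] %in% c("+", "-", ".")) {
      stop("GTF parse error at line ", i, ": unknown strand '", fields[[7]], "'")
    }
  }
  invisible(TRUE)
}

empty_exon_table <- function() {
  data.frame(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0),
    start = numeric(0), end = numeric(0),
    stringsAsFactors = FALSE
  )
}

check_exon_table <- function(exons) {
  needed <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!is.data.frame(exons) || !all(needed %in% names(exons))) {
    stop("exon table must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(exons) > 0L) {
    if (any(exons$start < 0) || any(exons$end <= exons$start)) {
      stop("exon table violates 0 <= start < end")
    }
    if (!all(exons$strand %in% c("+", "-", "."))) {
      stop("exon strand must be one of '+', '-', '.'")
    }
  }
  invisible(TRUE)
}

canonical_exon_order <- function(exons) {
  if (nrow(exons) == 0L) return(exons)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  span_start <- stats::ave(exons$start, exons$transcript_id, FUN = min)
  ord <- order(exons$chrom, span_start, exons$transcript_id, exons$start)
  out <- exons[ord, , drop = FALSE]
  rownames(out) <- NULL
  # exons of one transcript must be pairwise disjoint
  by_tx <- split(seq_len(nrow(out)), out$transcript_id)
  for (idx in by_tx) {
    s <- out$start[idx]; e <- out$end[idx]
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("overlapping exons within transcript ", out$transcript_id[idx[1L]])
    }
  }
  out
}

#' Per-transcript summaries of an exon table
#'
#' @param exons An exon table ([read_gtf()]).
#' @return One row per transcript: `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `n_exons`, `length` (sum of exon lengths, nt), `start` and
#'   `end` (locus span, 0-based half-open).
#' @export
transcript_stats <- function(exons) {
  check_exon_table(exons)
  if (nrow(exons) == 0L) {
    return(data.frame(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), strand = character(0),
      n_exons = integer(0), length = integer(0),
      start = integer(0), end = integer(0), stringsAsFactors = FALSE
    ))
  }
  exons <- canonical_exon_order(exons)
  first <- !duplicated(exons$transcript_id)
  ids <- exons$transcript_id[first]
  idx <- split(seq_len(nrow(exons)), factor(exons$transcript_id, levels = ids))
  data.frame(
    transcript_id = ids,
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    n_exons = lengths(idx),
    length = vapply(idx, function(i) sum(exons$end[i] - exons$start[i]), numeric(1)),
    start = vapply(idx, function(i) min(exons$start[i]), numeric(1)),
    end = vapply(idx, function(i) max(exons$end[i]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
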