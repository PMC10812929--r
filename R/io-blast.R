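#' Read tabular homology hits (BLAST outfmt 6)
#'
#' Parses the standard 12-column tab-separated hit format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) and attaches query lengths, which the coverage filter
#' needs but the format does not carry.
#'
#' @param path Hit table path (no header).
#' @param query_lengths Named numeric vector: query id -> sequence length
#'   (nt), e.g. `nchar(read_fasta(...))`.
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`,
#'   `query_length`.
#' @export
read_blast_tab <- function(path, query_lengths) {
  stopifnot(file.exists(path), is.numeric(query_lengths),
            !is.null(names(query_lengths)))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_hit_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("hit table parse error at line ", which(nf != 12L)[1L],
         ": expected 12 columns, got ", nf[nf != 12L][1L])
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = as.numeric(m[, 3L]),
    alignment_length = as.numeric(m[, 4L]),
    mismatches = as.numeric(m[, 5L]), gap_opens = as.numeric(m[, 6L]),
    qstart = as.numeric(m[, 7L]), qend = as.numeric(m[, 8L]),
    sstart = as.numeric(m[, 9L]), send = as.numeric(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) {
    stop("unparseable or negative E-value in ", path)
  }
  if (any(hits$alignment_length < 1)) {
    stop("alignment_length < 1 in ", path)
  }
  unknown <- setdiff(hits$query_id, names(query_lengths))
  if (length(unknown)) {
    stop("no query length for id(s): ", paste(unknown, collapse = ", "))
  }
  hits$query_length <- as.numeric(query_lengths[hits$query_id])
  hits
}

empty_hit_table <- function() {
  data.frame(
    query_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), alignment_length = numeric(0),
    mismatches = numeric(0), gap_opens = numeric(0),
    qstart = numeric(0), qend = numeric(0), sstart = numeric(0),
    send = numeric(0), evalue = numeric(0), bitscore = numeric(0),
    query_length = numeric(0), stringsAsFactors = FALSE
  )
}
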