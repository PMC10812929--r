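#' Filter parameters for lncRNA candidate selection
#'
#' @param min_length Minimum transcript length in nt (default 200).
#' @param min_exons Minimum exon count (default 1; monoexonic transcripts
#'   pass).
#' @param min_fpkm Minimum of the per-transcript maximum FPKM across all
#'   samples (default 0.5): a transcript well expressed in a single stage
#'   is kept.
#' @param require_unannotated Drop `=` transcripts first (default TRUE).
#' @return Named list of parameters.
#' @export
filter_params <- function(min_length = 200, min_exons = 1, min_fpkm = 0.5,
                          require_unannotated = TRUE) {
  stopifnot(min_length >= 0, min_exons >= 0, min_fpkm >= 0)
  list(min_length = min_length, min_exons = min_exons, min_fpkm = min_fpkm,
       require_unannotated = require_unannotated)
}

#' Apply the lncRNA candidate filter cascade
#'
#' The cascade, in order: (0) keep only unannotated positional classes
#' (`u`, `x`, `i`, `o`; drop `=`); (1) drop transcripts shorter than
#' `min_length` or with fewer than `min_exons` exons; (2) drop transcripts
#' whose maximum FPKM across all samples is below `min_fpkm`; (3) keep only
#' transcripts the coding-potential ensemble calls non-coding. Every step
#' is recorded in an audit table.
#'
#' @param transcripts Exon table of the candidate transcripts.
#' @param class_codes Output of [classify_transcripts()] covering every
#'   candidate.
#' @param fpkm_matrix FPKM matrix ([fpkm()]) with candidate transcripts in
#'   its rows.
#' @param verdicts Output of [ensemble_noncoding_vote()] (or
#'   [ingest_external_predictions()]) with `transcript_id` and
#'   `is_noncoding`; must cover the transcripts surviving steps 0-2.
#' @param params [filter_params()].
#' @return List with `records` (per-lncRNA table: `lncrna_id`,
#'   `transcript_id`, `category`, `class_code`, `chrom`, `strand`, `start`,
#'   `end`, `length`, `n_exons`) and `audit` (per-step `step`,
#'   `input_count`, `removed`, `surviving`, `parameter`).
#' @export
filter_candidates <- function(transcripts, class_codes, fpkm_matrix, verdicts,
                              params = filter_params()) {
  st <- transcript_stats(transcripts)
  miss <- setdiff(st$transcript_id, class_codes$transcript_id)
  if (length(miss)) {
    stop("transcripts without a class code: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  st$class_code <- class_codes$code[match(st$transcript_id, class_codes$transcript_id)]

  audit <- data.frame(step = character(0), input_count = integer(0),
                      removed = integer(0), surviving = integer(0),
                      parameter = character(0), stringsAsFactors = FALSE)
  record_step <- function(audit, name, before, after, parameter) {
    rbind(audit, data.frame(step = name, input_count = before,
                            removed = before - after, surviving = after,
                            parameter = parameter, stringsAsFactors = FALSE))
  }

  cur <- st
  if (params$require_unannotated) {
    before <- nrow(cur)
    cur <- cur[cur$class_code %in% c("u", "x", "i", "o"), , drop = FALSE]
    audit <- record_step(audit, "unannotated_class", before, nrow(cur),
                         "class in {u,x,i,o}")
  }

  before <- nrow(cur)
  cur <- cur[cur$length >= params$min_length & cur$n_exons >= params$min_exons, ,
             drop = FALSE]
  audit <- record_step(audit, "length_exons", before, nrow(cur),
                       sprintf("length >= %g nt, exons >= %g",
                               params$min_length, params$min_exons))

  miss <- setdiff(cur$transcript_id, rownames(fpkm_matrix))
  if (length(miss)) {
    stop("transcripts missing from the FPKM matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  before <- nrow(cur)
  max_fpkm <- apply(fpkm_matrix[cur$transcript_id, , drop = FALSE], 1L, max)
  cur <- cur[max_fpkm >= params$min_fpkm, , drop = FALSE]
  audit <- record_step(audit, "expression", before, nrow(cur),
                       sprintf("max FPKM >= %g", params$min_fpkm))

  miss <- setdiff(cur$transcript_id, verdicts$transcript_id)
  if (length(miss)) {
    stop("transcripts without a coding verdict: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  before <- nrow(cur)
  nc <- verdicts$is_noncoding[match(cur$transcript_id, verdicts$transcript_id)]
  cur <- cur[nc, , drop = FALSE]
  audit <- record_step(audit, "noncoding", before, nrow(cur),
                       "all three predictors non-coding")

  records <- data.frame(
    transcript_id = cur$transcript_id,
    class_code = cur$class_code,
    chrom = cur$chrom, strand = cur$strand,
    start = cur$start, end = cur$end,
    length = cur$length, n_exons = cur$n_exons,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  list(records = categorize_and_name(records), audit = audit)
}

#' Categorize surviving lncRNAs and assign stable names
#'
#' Class codes map deterministically to categories (`u` -> lincRNA, `x` ->
#' antisense, `o` -> sense, `i` -> intronic). Identifiers are
#' `TCONS_<8-digit serial>` assigned in genomic sort order (chrom, start,
#' transcript_id), so a fixed input set always yields the same names.
#'
#' @param records `data.frame` with at least `transcript_id`, `class_code`,
#'   `chrom`, `start`.
#' @return `records` with `category` and `lncrna_id` columns, sorted in
#'   naming order.
#' @export
categorize_and_name <- function(records) {
  category_map <- c(u = "lincRNA", x = "antisense", o = "sense", i = "intronic")
  unknown <- setdiff(records$class_code, names(category_map))
  if (length(unknown)) {
    stop("unknown class code(s): ", paste(unknown, collapse = ", "))
  }
  records$category <- unname(category_map[records$class_code])
  ord <- order(records$chrom, records$start, records$transcript_id)
  records <- records[ord, , drop = FALSE]
  records$lncrna_id <- sprintf("TCONS_%08d", seq_len(nrow(records)))
  rownames(records) <- NULL
  records[, c("lncrna_id", setdiff(names(records), "lncrna_id"))]
}
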