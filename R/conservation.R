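#' Filter homology hits by E-value and query coverage
#'
#' A hit is kept iff `evalue < max_evalue` (strict) and
#' `alignment_length / query_length >= min_coverage` (non-strict). Coverage
#' is computed against the query length by default; set
#' `coverage_on = "subject"` with a `subject_lengths` vector to use the
#' subject instead.
#'
#' @param hits Hit table from [read_blast_tab()].
#' @param max_evalue E-value cutoff (default `1e-10`).
#' @param min_coverage Coverage cutoff as a fraction (default 0.30).
#' @param coverage_on `"query"` (default) or `"subject"`.
#' @param subject_lengths Named vector, required for subject coverage.
#' @return Kept hits with an added `coverage` column.
#' @export
filter_hits <- function(hits, max_evalue = 1e-10, min_coverage = 0.30,
                        coverage_on = c("query", "subject"),
                        subject_lengths = NULL) {
  coverage_on <- match.arg(coverage_on)
  if (coverage_on == "query") {
    if (is.null(hits$query_length) || any(is.na(hits$query_length))) {
      stop("query_length missing from hit table")
    }
    denom <- hits$query_length
  } else {
    if (is.null(subject_lengths)) stop("subject_lengths required")
    denom <- as.numeric(subject_lengths[hits$subject_id])
    if (any(is.na(denom))) stop("subject length missing for some hits")
  }
  hits$coverage <- hits$alignment_length / denom
  out <- hits[hits$evalue < max_evalue & hits$coverage >= min_coverage, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best subject per query
#'
#' Best = maximum bitscore; ties broken by smaller E-value, then by
#' lexicographically smallest subject id, so the map is deterministic.
#'
#' @param hits Filtered hit table ([filter_hits()]).
#' @return Named character vector: query id -> best subject id. Queries
#'   without hits are absent.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[ord, ]
  h <- h[!duplicated(h$query_id), ]
  stats::setNames(h$subject_id, h$query_id)
}

#' Reciprocal best hits between two sequence sets
#'
#' `(q, s)` is a reciprocal best hit iff `forward[q] == s` and
#' `reverse[s] == q`, both maps computed with the same filters.
#'
#' @param forward,reverse [best_hit_per_query()] maps for the two
#'   directions.
#' @param species Species name recorded on each pair.
#' @return `data.frame` with `query_id`, `subject_id`, `species`.
#' @export
reciprocal_best_hits <- function(forward, reverse, species = NA_character_) {
  keep <- !is.na(reverse[forward]) & reverse[forward] == names(forward)
  keep[is.na(keep)] <- FALSE
  out <- data.frame(query_id = names(forward)[keep],
                    subject_id = unname(forward[keep]),
                    species = rep(species, sum(keep)),
                    stringsAsFactors = FALSE)
  out[order(out$query_id), , drop = FALSE]
}

#' Per-species conservation summary and cross-species sharing
#'
#' For each species: `n_conserved` = queries with at least one kept one-way
#' hit; `n_highly_conserved` = reciprocal-best-hit pairs. The sharing
#' matrix records, over the union of conserved query ids, membership per
#' species (the input for upset-style sharing plots).
#'
#' @param kept_hits Named list (by species) of filtered one-way hit tables.
#' @param rbh_pairs Named list (by species) of [reciprocal_best_hits()]
#'   tables.
#' @return List with `summary` (`species`, `n_conserved`,
#'   `n_highly_conserved`) and `sharing` (logical matrix, conserved query
#'   ids x species).
#' @export
conservation_summary <- function(kept_hits, rbh_pairs) {
  stopifnot(length(kept_hits) >= 1L, !is.null(names(kept_hits)))
  species <- names(kept_hits)
  conserved_ids <- lapply(kept_hits, function(h) sort(unique(h$query_id)))
  summary <- data.frame(
    species = species,
    n_conserved = vapply(conserved_ids, length, integer(1)),
    n_highly_conserved = vapply(species, function(sp) {
      if (is.null(rbh_pairs[[sp]])) 0L else nrow(rbh_pairs[[sp]])
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  all_ids <- sort(unique(unlist(conserved_ids)))
  sharing <- vapply(species, function(sp) all_ids %in% conserved_ids[[sp]],
                    logical(length(all_ids)))
  if (length(all_ids) == 1L) sharing <- matrix(sharing, nrow = 1L,
                                               dimnames = list(all_ids, species))
  else rownames(sharing) <- all_ids
  list(summary = summary, sharing = sharing)
}
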