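#' Cis targets: genes within a genomic window of each lncRNA
#'
#' A protein-coding gene is a cis-target candidate of an lncRNA when the
#' gap between the two locus spans on the same chromosome is at most
#' `window` bp, strand-agnostic. Overlapping loci have distance 0;
#' otherwise the distance is the inter-interval gap, so it is symmetric in
#' the two loci.
#'
#' @param lncrnas,genes `data.frame`s with `chrom`, `start`, `end` (0-based
#'   half-open locus spans) and an id column (`lncrna_id` / `gene_id`,
#'   falling back to `transcript_id`).
#' @param window Maximum gap in bp (default 100000, i.e. the 100-kb
#'   neighborhood; 10000 reproduces the narrower "adjacent" preset).
#' @return `data.frame` with `lncrna_id`, `gene_id`, `mode = "cis"`,
#'   `distance`.
#' @export
cis_targets <- function(lncrnas, genes, window = 100000) {
  stopifnot(window >= 0)
  lid <- lncrnas[[if ("lncrna_id" %in% names(lncrnas)) "lncrna_id" else "transcript_id"]]
  gid <- genes[[if ("gene_id" %in% names(genes)) "gene_id" else "transcript_id"]]
  l_gr <- GenomicRanges::GRanges(
    seqnames = lncrnas$chrom,
    ranges = IRanges::IRanges(start = lncrnas$start + 1L, end = lncrnas$end))
  g_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  ov <- GenomicRanges::findOverlaps(l_gr, g_gr, maxgap = window)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  gap <- pmax(0, pmax(lncrnas$start[qi], genes$start[si]) -
                 pmin(lncrnas$end[qi], genes$end[si]))
  out <- data.frame(lncrna_id = lid[qi], gene_id = gid[si],
                    mode = rep("cis", length(qi)),
                    distance = gap, stringsAsFactors = FALSE)
  out <- out[out$distance <= window, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors, equal length >= 3, both with nonzero
#'   variance.
#' @return List with `r` and `pvalue` (t-distribution, n - 2 df,
#'   two-sided).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3L) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), pvalue = ct$p.value)
}

#' Trans targets: expression-correlated genes
#'
#' A pair is kept iff `|r| >= min_abs_r` (non-strict) and the correlation
#' p-value is `< alpha`. Pairs where either vector has zero variance are
#' skipped with a warning.
#'
#' @param lnc_expr,gene_expr Expression (e.g. FPKM) matrices sharing the
#'   same sample columns; rows are lncRNAs / genes.
#' @param min_abs_r Correlation magnitude cutoff (default 0.95).
#' @param alpha Correlation p-value cutoff (default 0.05).
#' @return `data.frame` with `lncrna_id`, `gene_id`, `mode = "trans"`,
#'   `r`, `r_pvalue`.
#' @export
trans_targets <- function(lnc_expr, gene_expr, min_abs_r = 0.95, alpha = 0.05) {
  if (ncol(lnc_expr) != ncol(gene_expr) ||
      !all(colnames(lnc_expr) == colnames(gene_expr))) {
    stop("expression matrices must share the same sample columns")
  }
  n <- ncol(lnc_expr)
  if (n < 3L) stop("need >= 3 samples")
  lv <- apply(lnc_expr, 1L, stats::sd)
  gv <- apply(gene_expr, 1L, stats::sd)
  if (any(lv == 0) || any(gv == 0)) {
    warning(sum(lv == 0) + sum(gv == 0),
            " constant expression vector(s) skipped")
  }
  lm_ <- lnc_expr[lv > 0, , drop = FALSE]
  gm_ <- gene_expr[gv > 0, , drop = FALSE]
  if (nrow(lm_) == 0L || nrow(gm_) == 0L) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      mode = character(0), r = numeric(0),
                      r_pvalue = numeric(0), stringsAsFactors = FALSE))
  }
  r <- stats::cor(t(lm_), t(gm_))
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  pv <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  keep <- which(abs(r) >= min_abs_r & pv < alpha, arr.ind = TRUE)
  out <- data.frame(
    lncrna_id = rownames(lm_)[keep[, 1L]],
    gene_id = rownames(gm_)[keep[, 2L]],
    mode = rep("trans", nrow(keep)),
    r = r[keep], r_pvalue = pv[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric term enrichment
#'
#' For every term with at least one universe gene, the upper-tail
#' hypergeometric probability `P(X >= k)` of drawing `k` term genes in a
#' selection of size `n` from a universe of size `N` containing `K` term
#' genes, BH-adjusted across tested terms.
#'
#' @param selected_genes Character vector, subset of `universe_genes`.
#' @param universe_genes Character vector (the background, e.g. all
#'   expressed protein-coding genes).
#' @param term_map `data.frame` with columns `term_id` and `gene_id`
#'   (optionally `term_name`).
#' @param q_threshold Significance flag threshold (default 0.05).
#' @return `data.frame`: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `pvalue`, `qvalue`, `significant`.
#' @export
enrich <- function(selected_genes, universe_genes, term_map,
                   q_threshold = 0.05) {
  selected_genes <- unique(selected_genes)
  universe_genes <- unique(universe_genes)
  if (!all(selected_genes %in% universe_genes)) {
    stop("selected genes must be a subset of the universe")
  }
  stopifnot(all(c("term_id", "gene_id") %in% names(term_map)))
  term_map <- term_map[term_map$gene_id %in% universe_genes, , drop = FALSE]
  terms <- split(term_map$gene_id, term_map$term_id)
  terms <- terms[lengths(terms) >= 1L]
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), pvalue = numeric(0), qvalue = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  N <- length(universe_genes)
  n <- length(selected_genes)
  K <- vapply(terms, function(g) length(unique(g)), integer(1))
  k <- vapply(terms, function(g) length(intersect(unique(g), selected_genes)),
              integer(1))
  pv <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  name_col <- if ("term_name" %in% names(term_map)) {
    term_map$term_name[match(names(terms), term_map$term_id)]
  } else names(terms)
  out <- data.frame(term_id = names(terms), term_name = name_col,
                    k = k, K = K, n = n, N = N,
                    pvalue = pv, qvalue = bh_adjust(pv),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$qvalue < q_threshold
  out[order(out$pvalue, out$term_id), , drop = FALSE]
}

#' Export a target-pair edge table
#'
#' Flattens cis and trans pairs into a generic edge list (importable by
#' network tools), annotated with the differential-expression status of
#' both ends when available.
#'
#' @param pairs `data.frame` of target pairs ([cis_targets()] /
#'   [trans_targets()], possibly rbind-ed).
#' @param de_annotations Optional `data.frame` with `feature_id` and
#'   `status`.
#' @param path Optional output TSV path.
#' @return The edge `data.frame` (`source`, `target`, `mode`, `distance`,
#'   `r`, `source_status`, `target_status`), invisibly written to `path`
#'   when given.
#' @export
export_network <- function(pairs, de_annotations = NULL, path = NULL) {
  edges <- data.frame(
    source = pairs$lncrna_id,
    target = pairs$gene_id,
    mode = pairs$mode,
    distance = if ("distance" %in% names(pairs)) pairs$distance else NA_real_,
    r = if ("r" %in% names(pairs)) pairs$r else NA_real_,
    stringsAsFactors = FALSE
  )
  lookup <- function(ids) {
    if (is.null(de_annotations)) return(rep(NA_character_, length(ids)))
    de_annotations$status[match(ids, de_annotations$feature_id)]
  }
  edges$source_status <- lookup(edges$source)
  edges$target_status <- lookup(edges$target)
  if (!is.null(path)) write_tsv(edges, path)
  edges
}
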