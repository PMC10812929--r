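#' Construct an expression set from a count matrix
#'
#' The package's container for per-sample read counts: an integer matrix
#' with feature ids as rownames, per-sample library sizes and a condition
#' label per sample. Counts are always raw integers; FPKM is derived with
#' [fpkm()], never stored, so there is a single source of truth.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param groups Character vector of condition labels, one per sample
#'   (e.g. `"FB"`, `"FF"`).
#' @param library_sizes Total mapped reads per sample; defaults to column
#'   sums of `counts`.
#' @return An object of class `expr_set`: a list with elements `counts`,
#'   `library_sizes`, `groups`.
#' @export
expr_set <- function(counts, groups, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (length(groups) != ncol(counts)) {
    stop("one group label per sample required")
  }
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0)) {
    stop("library_sizes must be positive, one per sample")
  }
  structure(
    list(counts = counts,
         library_sizes = stats::setNames(library_sizes, colnames(counts)),
         groups = stats::setNames(as.character(groups), colnames(counts))),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s=%s", names(x$groups), x$groups), collapse = " "), "\n")
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' Group labels and library sizes may come from a sidecar sample table
#' (TSV with columns `sample`, `group` and optionally `library_size`); if
#' library sizes are absent they default to per-sample column sums.
#'
#' @param path Count matrix TSV.
#' @param samples_path Optional sample sheet TSV. When `NULL`, all samples
#'   get group label `"all"`.
#' @return An [expr_set()].
#' @export
read_counts <- function(path, samples_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count in ", path)
  rownames(mat) <- ids
  groups <- rep("all", ncol(mat))
  names(groups) <- colnames(mat)
  lib <- colSums(mat)
  if (!is.null(samples_path)) {
    st <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(st))) {
      stop("sample sheet needs columns 'sample' and 'group'")
    }
    miss <- setdiff(colnames(mat), st$sample)
    if (length(miss)) stop("samples missing from sheet: ", paste(miss, collapse = ", "))
    st <- st[match(colnames(mat), st$sample), ]
    groups <- st$group
    if ("library_size" %in% names(st) && !anyNA(st$library_size)) {
      lib <- st$library_size
    }
  }
  expr_set(mat, groups = groups, library_sizes = lib)
}

#' Write an expression set's counts (and sample sheet) as TSV
#'
#' @param es An [expr_set()].
#' @param path Count matrix output path.
#' @param samples_path Optional sample sheet output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(es, path, samples_path = NULL) {
  stopifnot(inherits(es, "expr_set"))
  df <- data.frame(feature_id = rownames(es$counts), es$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(samples_path)) {
    write_tsv(data.frame(sample = colnames(es$counts),
                         group = unname(es$groups),
                         library_size = unname(es$library_sizes),
                         stringsAsFactors = FALSE),
              samples_path)
  }
  invisible(path)
}

# deterministic TSV writer used for all tabular outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
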