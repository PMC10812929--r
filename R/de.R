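#' FPKM from raw counts
#'
#' `FPKM[f, s] = counts[f, s] * 1e9 / (length[f] * library_size[s])`.
#'
#' @param counts Count matrix (features x samples) or an [expr_set()].
#' @param lengths Named numeric vector of feature lengths (nt, > 0)
#'   covering every row.
#' @param library_sizes Per-sample totals (> 0); taken from the `expr_set`
#'   when one is supplied.
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
fpkm <- function(counts, lengths, library_sizes = NULL) {
  if (inherits(counts, "expr_set")) {
    if (is.null(library_sizes)) library_sizes <- counts$library_sizes
    counts <- counts$counts
  }
  stopifnot(!is.null(rownames(counts)), !is.null(names(lengths)))
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) {
    stop("no length for feature(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("feature lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts / len, 2L, library_sizes, "/") * 1e9
}

#' Method-of-moments negative-binomial dispersion per feature
#'
#' Counts are first scaled to a common library size (the mean), then a
#' within-group moment estimate `(s^2 - mu) / mu^2` is computed per group
#' and pooled across groups with degrees-of-freedom weights. Variance is
#' parameterized as `mu + phi * mu^2`. Estimates are floored (Poisson-like
#' and all-zero features sit at the floor).
#'
#' @param es An [expr_set()] with exactly two groups, >= 2 samples each.
#' @param floor Minimum dispersion (default `1e-6`).
#' @return `data.frame` with `feature_id`, `dispersion`, `flagged`
#'   (all-zero features).
#' @export
estimate_dispersion <- function(es, floor = 1e-6) {
  stopifnot(inherits(es, "expr_set"))
  groups <- unique(es$groups)
  if (any(table(es$groups) < 2L)) stop(">= 2 samples per group required")
  norm <- sweep(es$counts, 2L, mean(es$library_sizes) / es$library_sizes, "*")
  phi_g <- vapply(groups, function(g) {
    x <- norm[, es$groups == g, drop = FALSE]
    mu <- rowMeans(x)
    s2 <- apply(x, 1L, stats::var)
    ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
  }, numeric(nrow(es$counts)))
  phi_g <- matrix(phi_g, nrow = nrow(es$counts))
  w <- as.numeric(table(es$groups)[groups] - 1L)
  phi <- apply(phi_g, 1L, function(p) {
    ok <- !is.na(p)
    if (!any(ok)) return(NA_real_)
    sum(p[ok] * w[ok]) / sum(w[ok])
  })
  flagged <- is.na(phi)
  phi[flagged] <- floor
  data.frame(feature_id = rownames(es$counts),
             dispersion = pmax(floor, phi),
             flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' Conditions on the pooled sum of the (library-size-equalized) group
#' totals: with group sums `a + b = s`, each possible split `(a, s - a)`
#' has probability proportional to the product of the two group-sum NB
#' densities (group sum of n iid NB(mu, phi) is NB(n*mu, phi/n)). The
#' two-sided p-value is the total probability of all splits no more
#' probable than the observed one. With `phi = 0` the NB degenerates to
#' Poisson and the conditional distribution is the exact binomial split.
#'
#' @param a_counts,b_counts Non-negative integer count vectors for the two
#'   groups (one feature).
#' @param phi NB dispersion (>= 0).
#' @param norm_factors Optional list with `a` and `b` numeric vectors of
#'   effective library sizes for each sample; counts are scaled to their
#'   mean before summing. Default: all equal (no scaling).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(a_counts, b_counts, phi, norm_factors = NULL) {
  if (any(c(a_counts, b_counts) < 0) ||
      any(c(a_counts, b_counts) != round(c(a_counts, b_counts)))) {
    stop("counts must be non-negative integers")
  }
  stopifnot(phi >= 0)
  na <- length(a_counts); nb <- length(b_counts)
  if (!is.null(norm_factors)) {
    ref <- mean(c(norm_factors$a, norm_factors$b))
    a_counts <- round(a_counts * ref / norm_factors$a)
    b_counts <- round(b_counts * ref / norm_factors$b)
  }
  s <- sum(a_counts) + sum(b_counts)
  if (s == 0) return(1)
  obs_a <- sum(a_counts)
  a <- 0:s
  prop_a <- na / (na + nb)
  if (phi < 1e-12) {
    # Poisson limit: conditional distribution of the A-sum is binomial
    logp <- stats::dbinom(a, size = s, prob = prop_a, log = TRUE)
  } else {
    mu <- s / (na + nb)  # per-sample mean under the null
    logp <- stats::dnbinom(a, size = na / phi, mu = na * mu, log = TRUE) +
      stats::dnbinom(s - a, size = nb / phi, mu = nb * mu, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs_p <- p[obs_a + 1L]
  min(1, sum(p[p <= obs_p * (1 + 1e-10)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, monotone in p, with the original order restored.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression status calls
#'
#' Strict thresholds: `up` when `log2fc > lfc_threshold` and
#' `q < q_threshold`; `down` when `log2fc < -lfc_threshold` and
#' `q < q_threshold`; otherwise `ns`.
#'
#' @param results `data.frame` with `log2fc` and `qvalue` columns.
#' @param lfc_threshold,q_threshold Thresholds (defaults 1 and 0.05).
#' @return `results` with a `status` column.
#' @export
call_de <- function(results, lfc_threshold = 1, q_threshold = 0.05) {
  status <- rep("ns", nrow(results))
  status[results$log2fc > lfc_threshold & results$qvalue < q_threshold] <- "up"
  status[results$log2fc < -lfc_threshold & results$qvalue < q_threshold] <- "down"
  results$status <- status
  results
}

empty_de_table <- function() {
  data.frame(feature_id = character(0), base_mean_a = numeric(0),
             base_mean_b = numeric(0), log2fc = numeric(0),
             dispersion = numeric(0), pvalue = numeric(0),
             qvalue = numeric(0), status = character(0),
             stringsAsFactors = FALSE)
}

#' Two-condition differential expression with the NB exact test
#'
#' Per feature: pooled method-of-moments dispersion, NB exact test on the
#' two groups with library-size normalization, log2 fold change of
#' normalized means with a pseudo-count of 0.5, BH adjustment across
#' features, and status calls. The fold change is
#' `log2(mean(group_b) / mean(group_a))` on library-size-normalized
#' counts, i.e. positive values mean higher in `group_b`.
#'
#' @param es An [expr_set()] with exactly two groups.
#' @param group_a,group_b Group labels; defaults to the two labels in
#'   order of first appearance (`group_a` is the baseline).
#' @param lfc_threshold,q_threshold Status-call thresholds.
#' @param dispersion_floor Floor for the dispersion estimate.
#' @return `data.frame`: `feature_id`, `base_mean_a`, `base_mean_b`,
#'   `log2fc`, `dispersion`, `pvalue`, `qvalue`, `status`.
#' @export
de_test <- function(es, group_a = NULL, group_b = NULL,
                    lfc_threshold = 1, q_threshold = 0.05,
                    dispersion_floor = 1e-6) {
  stopifnot(inherits(es, "expr_set"))
  labs <- unique(es$groups)
  if (length(labs) != 2L) stop("exactly two groups required")
  if (is.null(group_a)) group_a <- labs[1L]
  if (is.null(group_b)) group_b <- labs[2L]
  ia <- which(es$groups == group_a)
  ib <- which(es$groups == group_b)
  disp <- estimate_dispersion(es, floor = dispersion_floor)
  ref <- mean(es$library_sizes)
  norm <- sweep(es$counts, 2L, ref / es$library_sizes, "*")
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  pvals <- vapply(seq_len(nrow(es$counts)), function(i) {
    nb_exact_test(es$counts[i, ia], es$counts[i, ib], disp$dispersion[i],
                  norm_factors = list(a = es$library_sizes[ia],
                                      b = es$library_sizes[ib]))
  }, numeric(1))
  res <- data.frame(
    feature_id = rownames(es$counts),
    base_mean_a = mean_a, base_mean_b = mean_b,
    log2fc = log2fc, dispersion = disp$dispersion,
    pvalue = pvals, qvalue = bh_adjust(pvals),
    row.names = NULL, stringsAsFactors = FALSE
  )
  call_de(res, lfc_threshold = lfc_threshold, q_threshold = q_threshold)
}
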