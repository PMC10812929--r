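#' Run configuration for the full pipeline
#'
#' @param input_dir Directory with the pipeline inputs, laid out as
#'   written by [generate_bundle()]: `reference.gtf`, `novel.gtf`,
#'   `novel.fa`, `counts.tsv`, `samples.tsv`, `training_coding.fa`,
#'   `training_noncoding.fa`, optional `term_map.tsv`, `chrom_sizes.tsv`
#'   and a `homology/` directory of per-species hit tables.
#' @param output_dir Where stage outputs are written.
#' @param filter [filter_params()].
#' @param thresholds [coding_thresholds()].
#' @param group_a,group_b Baseline and contrast condition labels
#'   (defaults `FB`, `FF`; fold changes are `log2(group_b / group_a)`).
#' @param lfc_threshold,q_threshold DE status thresholds.
#' @param max_evalue,min_coverage Conservation filters.
#' @param cis_window Cis-target window in bp (default 100000; 10000 gives
#'   the narrower "adjacent gene" preset).
#' @param min_abs_r,alpha Trans-target correlation cutoffs.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       filter = filter_params(),
                       thresholds = coding_thresholds(),
                       group_a = "FB", group_b = "FF",
                       lfc_threshold = 1, q_threshold = 0.05,
                       max_evalue = 1e-10, min_coverage = 0.30,
                       cis_window = 100000, min_abs_r = 0.95, alpha = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `filter` and `thresholds`
#' may be nested maps.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("filter", "thresholds"))]
  if (!is.null(y$filter)) args$filter <- do.call(filter_params, y$filter)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(coding_thresholds, y$thresholds)
  do.call(run_config, args)
}

#' Run the complete lncRNA identification pipeline
#'
#' Stages, in order: positional classification of the novel transcripts
#' against the reference annotation; coding-potential scoring and the
#' intersection vote; the candidate filter cascade with audit;
#' FPKM; differential expression (lncRNAs and protein-coding genes,
#' BH-adjusted separately); conservation from per-species homology tables
#' (one-way kept hits and reciprocal best hits); cis and trans target
#' prediction for the DE lncRNAs; hypergeometric term enrichment of the
#' target sets; and a summary report whose accounting identities are
#' verified with [check_accounting()]. The pipeline itself draws no random
#' numbers, so a rerun on the same inputs is bit-identical.
#'
#' @param config A [run_config()].
#' @return The summary report (list, also written as
#'   `report.json`), invisibly including all stage tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ind <- config$input_dir
  outd <- config$output_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)

  ref <- read_gtf(file.path(ind, "reference.gtf"))
  novel <- read_gtf(file.path(ind, "novel.gtf"))
  seqs <- read_fasta(file.path(ind, "novel.fa"))
  es <- read_counts(file.path(ind, "counts.tsv"), file.path(ind, "samples.tsv"))

  # --- classification
  idx <- build_reference_index(ref)
  codes <- classify_transcripts(novel, idx)
  write_tsv(codes, file.path(outd, "class_codes.tsv"))

  # --- coding potential
  cm <- train_hexamer_model(read_fasta(file.path(ind, "training_coding.fa")))
  ncm <- train_hexamer_model(read_fasta(file.path(ind, "training_noncoding.fa")))
  verdicts <- ensemble_noncoding_vote(
    score_coding_potential(seqs, cm, ncm), config$thresholds)
  write_tsv(verdicts, file.path(outd, "coding_verdicts.tsv"))

  # --- FPKM (novel transcripts + reference genes)
  nov_st <- transcript_stats(novel)
  ref_st <- transcript_stats(ref)
  gene_len <- tapply(ref_st$length, ref_st$gene_id, max)
  lengths <- c(stats::setNames(nov_st$length, nov_st$transcript_id),
               stats::setNames(as.numeric(gene_len), names(gene_len)))
  fpkm_all <- fpkm(es, lengths)
  write_tsv(data.frame(feature_id = rownames(fpkm_all), round(fpkm_all, 4),
                       check.names = FALSE), file.path(outd, "fpkm.tsv"))

  # --- filter cascade
  flt <- filter_candidates(novel, codes, fpkm_all, verdicts, config$filter)
  write_tsv(flt$records, file.path(outd, "lncrnas.tsv"))
  write_tsv(flt$audit, file.path(outd, "filter_audit.tsv"))
  lnc_ids <- flt$records$transcript_id
  write_gtf(novel[novel$transcript_id %in% lnc_ids, , drop = FALSE],
            file.path(outd, "lncrna.gtf"))

  # --- differential expression (separately for lncRNAs and PCGs)
  gene_ids <- sort(unique(ref_st$gene_id))
  subset_es <- function(ids) {
    expr_set(es$counts[ids, , drop = FALSE], groups = es$groups,
             library_sizes = es$library_sizes)
  }
  de_lnc <- if (length(lnc_ids)) {
    de_test(subset_es(lnc_ids), config$group_a, config$group_b,
            config$lfc_threshold, config$q_threshold)
  } else empty_de_table()
  de_pcg <- de_test(subset_es(intersect(gene_ids, rownames(es$counts))),
                    config$group_a, config$group_b,
                    config$lfc_threshold, config$q_threshold)
  write_tsv(de_lnc, file.path(outd, "de_lncrna.tsv"))
  write_tsv(de_pcg, file.path(outd, "de_pcg.tsv"))

  # --- conservation
  cons <- run_conservation(ind, seqs, lnc_ids, config)
  if (!is.null(cons)) {
    write_tsv(cons$summary, file.path(outd, "conservation_summary.tsv"))
    write_tsv(data.frame(query_id = rownames(cons$sharing),
                         cons$sharing * 1L, check.names = FALSE),
              file.path(outd, "conservation_sharing.tsv"))
    write_tsv(cons$rbh, file.path(outd, "rbh_pairs.tsv"))
  }

  # --- cis and trans targets of the DE lncRNAs
  de_lnc_ids <- de_lnc$feature_id[de_lnc$status != "ns"]
  de_recs <- flt$records[flt$records$transcript_id %in% de_lnc_ids, , drop = FALSE]
  de_recs$lncrna_id <- de_recs$transcript_id  # target tables use transcript ids
  gene_span <- ref_gene_spans(ref_st)
  cis <- cis_targets(de_recs, gene_span, window = config$cis_window)
  expressed_pcg <- gene_ids[apply(
    fpkm_all[gene_ids, , drop = FALSE], 1L, max) >= config$filter$min_fpkm]
  trans <- if (length(de_lnc_ids) && length(expressed_pcg)) {
    trans_targets(fpkm_all[de_lnc_ids, , drop = FALSE],
                  fpkm_all[expressed_pcg, , drop = FALSE],
                  min_abs_r = config$min_abs_r, alpha = config$alpha)
  } else {
    data.frame(lncrna_id = character(0), gene_id = character(0),
               mode = character(0), r = numeric(0), r_pvalue = numeric(0))
  }
  write_tsv(cis, file.path(outd, "cis_targets.tsv"))
  write_tsv(trans, file.path(outd, "trans_targets.tsv"))

  # --- enrichment of target gene sets
  tm_path <- file.path(ind, "term_map.tsv")
  enr_cis <- enr_trans <- NULL
  if (file.exists(tm_path) && length(expressed_pcg)) {
    term_map <- utils::read.delim(tm_path, stringsAsFactors = FALSE)
    enr_cis <- enrich(intersect(unique(cis$gene_id), expressed_pcg),
                      expressed_pcg, term_map)
    enr_trans <- enrich(intersect(unique(trans$gene_id), expressed_pcg),
                        expressed_pcg, term_map)
    write_tsv(enr_cis, file.path(outd, "enrichment_cis.tsv"))
    write_tsv(enr_trans, file.path(outd, "enrichment_trans.tsv"))
  }

  # --- network edge table
  de_ann <- rbind(de_lnc[c("feature_id", "status")], de_pcg[c("feature_id", "status")])
  cis_e <- cis
  cis_e$r <- rep(NA_real_, nrow(cis_e))
  cis_e$r_pvalue <- rep(NA_real_, nrow(cis_e))
  trans_e <- trans
  trans_e$distance <- rep(NA_real_, nrow(trans_e))
  cols <- c("lncrna_id", "gene_id", "mode", "distance", "r", "r_pvalue")
  all_pairs <- rbind(cis_e[cols], trans_e[cols])
  export_network(all_pairs, de_ann, file.path(outd, "network_edges.tsv"))

  # --- report
  chars <- if (length(lnc_ids)) {
    summarize_characteristics(
      novel[novel$transcript_id %in% lnc_ids, , drop = FALSE], ref)
  } else NULL
  cat_counts <- table(factor(flt$records$category,
                             levels = c("lincRNA", "antisense", "sense", "intronic")))
  de_status_lnc <- table(factor(de_lnc$status, levels = c("up", "down", "ns")))
  de_status_pcg <- table(factor(de_pcg$status, levels = c("up", "down", "ns")))
  de_by_cat <- table(factor(
    flt$records$category[match(de_lnc_ids, flt$records$transcript_id)],
    levels = c("lincRNA", "antisense", "sense", "intronic")))
  report <- list(
    parameters = config[setdiff(names(config), c("input_dir", "output_dir"))],
    n_novel = nrow(nov_st),
    class_counts = as.list(table(codes$code)),
    n_lncrna = nrow(flt$records),
    category_counts = as.list(cat_counts),
    audit = flt$audit,
    characteristics = chars,
    de_lncrna = list(up = unname(de_status_lnc[["up"]]),
                     down = unname(de_status_lnc[["down"]]),
                     ns = unname(de_status_lnc[["ns"]]),
                     total_de = unname(de_status_lnc[["up"]] + de_status_lnc[["down"]])),
    de_pcg = list(up = unname(de_status_pcg[["up"]]),
                  down = unname(de_status_pcg[["down"]]),
                  ns = unname(de_status_pcg[["ns"]]),
                  total_de = unname(de_status_pcg[["up"]] + de_status_pcg[["down"]])),
    de_lncrna_by_category = as.list(de_by_cat),
    conservation = if (is.null(cons)) NULL else cons$summary,
    cis = list(n_pairs = nrow(cis),
               n_lncrnas = length(unique(cis$lncrna_id)),
               mean_targets_per_lncrna = if (length(unique(cis$lncrna_id)))
                 nrow(cis) / length(unique(cis$lncrna_id)) else 0),
    trans = list(n_pairs = nrow(trans),
                 n_lncrnas = length(unique(trans$lncrna_id)),
                 n_genes = length(unique(trans$gene_id))),
    enrichment = list(
      n_significant_cis = if (is.null(enr_cis)) NA else sum(enr_cis$significant),
      n_significant_trans = if (is.null(enr_trans)) NA else sum(enr_trans$significant))
  )
  check_accounting(report)
  jsonlite::write_json(report, file.path(outd, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(c(report, list(
    lncrnas = flt$records, class_codes = codes, verdicts = verdicts,
    de_lnc_table = de_lnc, de_pcg_table = de_pcg,
    cis_pairs = cis, trans_pairs = trans, rbh = if (is.null(cons)) NULL else cons$rbh
  )))
}

# reference gene locus spans from per-transcript stats
ref_gene_spans <- function(ref_st) {
  sp <- data.frame(
    gene_id = ref_st$gene_id, chrom = ref_st$chrom,
    start = as.numeric(tapply(ref_st$start, ref_st$gene_id, min)[ref_st$gene_id]),
    end = as.numeric(tapply(ref_st$end, ref_st$gene_id, max)[ref_st$gene_id]),
    stringsAsFactors = FALSE)
  sp[!duplicated(sp$gene_id), , drop = FALSE]
}

# conservation stage over a homology/ directory; NULL when absent
run_conservation <- function(ind, seqs, lnc_ids, config) {
  hd <- file.path(ind, "homology")
  if (!dir.exists(hd)) return(NULL)
  fwd_files <- list.files(hd, pattern = "_forward\\.tsv$", full.names = TRUE)
  if (length(fwd_files) == 0L) return(NULL)
  species <- sub("_forward\\.tsv$", "", basename(fwd_files))
  qlen <- nchar(seqs)
  kept <- list(); rbh <- list()
  for (sp in species) {
    sp_seqs <- read_fasta(file.path(hd, paste0(sp, ".fa")))
    f <- read_blast_tab(file.path(hd, paste0(sp, "_forward.tsv")), qlen)
    r <- read_blast_tab(file.path(hd, paste0(sp, "_reverse.tsv")), nchar(sp_seqs))
    f <- f[f$query_id %in% lnc_ids, , drop = FALSE]
    r <- r[r$subject_id %in% lnc_ids, , drop = FALSE]
    fk <- filter_hits(f, config$max_evalue, config$min_coverage)
    rk <- filter_hits(r, config$max_evalue, config$min_coverage)
    kept[[sp]] <- fk
    rbh[[sp]] <- reciprocal_best_hits(best_hit_per_query(fk),
                                      best_hit_per_query(rk), species = sp)
  }
  cs <- conservation_summary(kept, rbh)
  list(summary = cs$summary, sharing = cs$sharing,
       rbh = do.call(rbind, c(rbh, list(make.row.names = FALSE))))
}

#' Verify the report's accounting identities
#'
#' The partition identities any consistent run must satisfy: category
#' counts partition the lncRNA total; up + down equals the DE total for
#' both feature types; per-category DE counts partition the DE lncRNA
#' total; and highly conserved counts never exceed conserved counts.
#'
#' @param report A [run_pipeline()] report.
#' @return `TRUE` invisibly, or an error describing the violated identity.
#' @export
check_accounting <- function(report) {
  if (sum(unlist(report$category_counts)) != report$n_lncrna) {
    stop("category counts do not partition the lncRNA total")
  }
  for (w in c("de_lncrna", "de_pcg")) {
    d <- report[[w]]
    if (d$up + d$down != d$total_de) {
      stop("up + down != total DE for ", w)
    }
  }
  if (sum(unlist(report$de_lncrna_by_category)) != report$de_lncrna$total_de) {
    stop("per-category DE lncRNA counts do not partition the DE total")
  }
  cons <- report$conservation
  if (!is.null(cons) && any(cons$n_highly_conserved > cons$n_conserved)) {
    stop("highly conserved exceeds conserved for some species")
  }
  invisible(TRUE)
}

#' Length and exon-count characteristics of two transcript sets
#'
#' The usual lncRNA-versus-mRNA contrast: mean and median transcript
#' length, the fraction of transcripts in the 201-1000 nt bin and above
#' 1000 nt, the mean exon count and the exon-count histogram.
#'
#' @param lnc_exons,mrna_exons Non-empty exon tables of the two sets.
#' @return `data.frame`, one row per set.
#' @export
summarize_characteristics <- function(lnc_exons, mrna_exons) {
  one <- function(exons, label) {
    st <- transcript_stats(exons)
    if (nrow(st) == 0L) stop("empty transcript set: ", label)
    ex_hist <- table(factor(pmin(st$n_exons, 5L), levels = 1:5))
    data.frame(
      set = label, n = nrow(st),
      mean_length = mean(st$length), median_length = stats::median(st$length),
      frac_201_1000 = mean(st$length >= 201 & st$length <= 1000),
      frac_gt_1000 = mean(st$length > 1000),
      mean_exons = mean(st$n_exons),
      exons_1 = unname(ex_hist[["1"]]), exons_2 = unname(ex_hist[["2"]]),
      exons_3 = unname(ex_hist[["3"]]), exons_4 = unname(ex_hist[["4"]]),
      exons_5plus = unname(ex_hist[["5"]]),
      stringsAsFactors = FALSE
    )
  }
  rbind(one(lnc_exons, "lncRNA"), one(mrna_exons, "mRNA"))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; `ddCt` subtracts the
#' mean `dCt` of the calibrator group; relative expression is `2^-ddCt`,
#' so the calibrator group averages 1 on the `ddCt` scale.
#'
#' @param ct_table Long-format `data.frame` with columns `sample`,
#'   `group`, `gene`, `ct`.
#' @param target_id Gene of interest.
#' @param reference_id Internal reference (housekeeping) gene.
#' @param control_group Calibrator group label.
#' @return `data.frame`: `sample`, `group`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`.
#' @export
ddct <- function(ct_table, target_id, reference_id, control_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct_table)))
  samples <- unique(ct_table$sample)
  get_ct <- function(gene) {
    ct <- ct_table$ct[match(paste(samples, gene),
                            paste(ct_table$sample, ct_table$gene))]
    if (anyNA(ct)) {
      stop("missing Ct for ", gene, " in sample(s): ",
           paste(samples[is.na(ct)], collapse = ", "))
    }
    ct
  }
  d_ct <- get_ct(target_id) - get_ct(reference_id)
  group <- ct_table$group[match(samples, ct_table$sample)]
  if (!control_group %in% group) stop("control group not present: ", control_group)
  dd_ct <- d_ct - mean(d_ct[group == control_group])
  data.frame(sample = samples, group = group, delta_ct = d_ct,
             delta_delta_ct = dd_ct, rel_expr = 2^(-dd_ct),
             stringsAsFactors = FALSE)
}
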