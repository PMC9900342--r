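#' Compare called clusters with planted truth
#'
#' A truth cluster is recovered iff some called cluster overlaps it with a
#' Jaccard (intersection over union) of at least `min_jaccard`; a called
#' cluster is spurious iff it overlaps no truth cluster at all.
#'
#' @param called data.frame from [call_clusters()].
#' @param truth Truth-cluster data.frame (`chrom`, `start`, `end`).
#' @param min_jaccard Minimum intersection/union for recovery.
#' @return List with `recall`, `spurious_rate`, `n_called`, `n_truth`.
#' @export
cluster_recovery <- function(called, truth, min_jaccard = 0.5) {
  assert_cols(truth, c("chrom", "start", "end"))
  if (nrow(called) == 0L)
    return(list(recall = 0, spurious_rate = 0, n_called = 0L,
                n_truth = nrow(truth)))
  cg <- as_granges0(called)
  tg <- as_granges0(truth)
  ov <- GenomicRanges::findOverlaps(cg, tg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(cg[qh], tg[sh]))
  uni <- GenomicRanges::width(cg[qh]) + GenomicRanges::width(tg[sh]) - inter
  jac <- inter / uni
  recovered <- unique(sh[jac >= min_jaccard])
  spurious <- setdiff(seq_along(cg), unique(qh))
  list(recall = length(recovered) / length(tg),
       spurious_rate = length(spurious) / length(cg),
       n_called = length(cg), n_truth = length(tg))
}

#' Run the full analysis pipeline on simulated or supplied data
#'
#' Executes the stage chain trim -> ncRNA filter -> reference match ->
#' genome alignment -> cluster calling -> `-f 1` counting -> sequence
#' characterization -> cluster differential expression -> in-silico target
#' prediction -> target-vs-nontarget statistics, logging record counts per
#' stage, and returns (plus optionally writes) a machine-readable summary.
#'
#' @param config Run configuration from [default_config()] (thresholds).
#' @param inputs Optional input bundle: list with elements `genome` (named
#'   character vector), `pirna_ref`, `ncrna`, `reads` (data.frame with
#'   `sequence`, `quality_string`, `sample`), and optionally `truth_clusters`.
#'   When `NULL` and `config$simulate` is `TRUE`, data are simulated from
#'   `sim_cfg`.
#' @param sim_cfg Optional [sim_config()]; defaults to
#'   `sim_config(seed = config$seed)`.
#' @param outdir Output directory for stage artifacts and `summary.json`;
#'   `NULL` suppresses writing.
#' @return List with all stage objects and `summary`.
#' @export
run_pipeline <- function(config = default_config(), inputs = NULL,
                         sim_cfg = NULL, outdir = NULL) {
  t0 <- Sys.time()
  truth <- NULL
  sim <- NULL
  if (is.null(inputs)) {
    if (!isTRUE(config$simulate))
      stopf("no inputs supplied and config$simulate is FALSE")
    sim_cfg <- sim_cfg %||% sim_config(seed = config$seed)
    genome_obj <- sim_genome(sim_cfg)
    ncrna <- sim_ncrna(sim_cfg)
    rd <- sim_reads(sim_cfg, genome_obj, ncrna)
    inputs <- list(genome = genome_obj$genome,
                   pirna_ref = genome_obj$pirna_ref,
                   ncrna = ncrna, reads = rd$reads,
                   truth_clusters = genome_obj$clusters)
    truth <- rd$truth
    sim <- list(genome = genome_obj, reads = rd,
                expected_cluster_prob = rd$expected_cluster_prob)
  }
  crit <- match_criteria(min_identity = config$min_identity,
                         max_mismatches = config$max_mismatches,
                         min_query_coverage = config$min_query_coverage,
                         max_hits_reported = config$max_hits_reported,
                         orientations = config$orientations)

  trimmed <- trim_reads(inputs$reads, adapter = config$adapter,
                        min_quality = config$min_quality,
                        min_length = config$min_length,
                        error_rate = config$adapter_error_rate,
                        min_overlap = config$adapter_min_overlap)
  filtered <- filter_ncrna(trimmed$reads, inputs$ncrna, crit)
  retained <- filtered$retained

  matched <- match_pirbase(retained, inputs$pirna_ref)
  aligned <- align_genome(retained, inputs$genome, cap = config$alignment_cap)

  matched_seqs <- unique(matched$matched$sequence)
  ann <- aligned[aligned$sequence %in% matched_seqs, , drop = FALSE]
  ann$name <- ann$sequence
  clusters <- call_clusters(ann)
  counts <- count_cluster_reads(aligned, clusters, retained)

  ldist <- length_distribution(matched$matched)
  bias <- five_prime_bias(matched$matched)
  assigned <- assign_cluster_reads(aligned, clusters)
  classified <- classify_primary_secondary(assigned)
  profile <- distance_probability(classified, window = config$distance_window,
                                  span = config$lowess_span)

  # cluster differential expression between the first two conditions with
  # at least two samples each (skipped otherwise)
  de_clusters <- NULL
  sample_cond <- NULL
  if (!is.null(sim_cfg)) sample_cond <- sim_cfg$samples
  if (!is.null(sim) || !is.null(sample_cond)) {
    sc <- sample_cond[match(colnames(counts), sample_cond$sample), ]
    tab <- table(sc$condition)
    use <- names(tab)[tab >= 2L][1:2]
    if (length(use) == 2L && !anyNA(use) && nrow(counts) > 1L) {
      sel <- sc$condition %in% use
      de_clusters <- differential_features(
        round(counts[, sel, drop = FALSE]), sc$condition[sel],
        padj_threshold = config$padj_threshold,
        lfc_threshold = config$lfc_threshold)
    }
  }

  # knockdown expression + in-silico targets (simulated inputs only)
  targets <- NULL; ks <- NULL; de_genes <- NULL; rho <- NULL
  if (!is.null(sim)) {
    tx <- sim_transcriptome(inputs$pirna_ref, n_genes = 200L,
                            seed = sim_cfg$seed)
    kd <- sim_expression(sim_cfg, target_genes = unique(tx$truth$gene_id))
    de_genes <- differential_features(kd$counts, kd$conditions,
                                      padj_threshold = config$padj_threshold,
                                      lfc_threshold = config$lfc_threshold)
    # piRNA abundance (TPM across samples) for the matched set
    msum <- stats::aggregate(count ~ sequence, matched$matched, sum)
    msum <- msum[order(-msum$count), , drop = FALSE]
    top <- utils::head(msum, 500L)
    ptpm <- top$count / sum(msum$count) * 1e6
    pir <- df(id = paste0("pir_", seq_len(nrow(top))),
              sequence = top$sequence, tpm = ptpm)
    targets <- predict_targets(pir, tx$transcripts, crit)
    rep_fc <- merge(targets$reports,
                    de_genes[, c("feature", "log2FoldChange", "call")],
                    by.x = "gene_id", by.y = "feature")
    rep_fc$modulated <- rep_fc$call != "unchanged"
    targets$reports <- rep_fc
    tfc <- rep_fc$log2FoldChange[rep_fc$is_target]
    nfc <- rep_fc$log2FoldChange[!rep_fc$is_target]
    if (length(tfc) && length(nfc)) ks <- ks_compare(tfc, nfc)
    if (sum(rep_fc$is_target) >= 3L) {
      sel <- rep_fc$is_target
      if (stats::sd(rep_fc$summed_targeting_tpm[sel]) > 0 &&
          stats::sd(rep_fc$log2FoldChange[sel]) > 0)
        rho <- spearman_targets(rep_fc$summed_targeting_tpm[sel],
                                rep_fc$log2FoldChange[sel])
    }
  }

  summary <- list(
    n_reads_raw = nrow(inputs$reads),
    n_retained_after_trim = trimmed$stats$n_retained,
    n_unique_after_trim = trimmed$stats$n_unique,
    n_removed_ncrna = filtered$stats$n_removed,
    n_putative_pirnas = sum(retained$count),
    n_matched_pirnas = matched$stats$multiplicity_matched,
    n_unique_matched = length(unique(matched$matched$sequence)),
    n_aligned_sequences = length(unique(aligned$sequence)),
    n_clusters = nrow(clusters),
    mean_cluster_length = if (nrow(clusters)) mean(clusters$length) else NA,
    mode_read_length = ldist$mode,
    u1_fraction = bias$u1_fraction,
    distance_argmax_raw = if (nrow(profile$profile))
      profile$profile$distance[which.max(profile$profile$probability)] else NA,
    distance_argmax_smoothed = if (nrow(profile$profile))
      profile$profile$distance[which.max(profile$profile$smoothed)] else NA,
    de_clusters_up = if (!is.null(de_clusters)) sum(de_clusters$call == "up") else NA,
    de_clusters_down = if (!is.null(de_clusters)) sum(de_clusters$call == "down") else NA,
    de_genes_up = if (!is.null(de_genes)) sum(de_genes$call == "up") else NA,
    de_genes_down = if (!is.null(de_genes)) sum(de_genes$call == "down") else NA,
    max_target_load = if (!is.null(targets))
      max(targets$reports$n_unique_targeting_pirnas) else NA,
    ks_D = if (!is.null(ks)) ks$statistic else NA,
    ks_p = if (!is.null(ks)) ks$p.value else NA,
    spearman_rho = if (!is.null(rho)) rho$rho else NA,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(inputs$truth_clusters)) {
    rec <- cluster_recovery(clusters, inputs$truth_clusters)
    summary$cluster_recall <- rec$recall
    summary$spurious_cluster_rate <- rec$spurious_rate
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(outdir, "config.json"))
    utils::write.table(clusters, file.path(outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix(counts, file.path(outdir, "cluster_counts.tsv"),
                 feature_col = "cluster")
    if (nrow(profile$profile))
      utils::write.table(profile$profile,
                         file.path(outdir, "distance_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(de_clusters))
      utils::write.table(de_clusters, file.path(outdir, "de_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(targets))
      utils::write.table(targets$reports,
                         file.path(outdir, "target_reports.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(config = config, trimmed = trimmed, filtered = filtered,
                 matched = matched, aligned = aligned, clusters = clusters,
                 counts = counts, length_dist = ldist, bias = bias,
                 profile = profile, de_clusters = de_clusters,
                 de_genes = de_genes, targets = targets, ks = ks,
                 spearman = rho, truth = truth,
                 expected_cluster_prob = if (!is.null(sim))
                   sim$expected_cluster_prob else NULL,
                 summary = summary))
}
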