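#' Categorize piRNA loci by genomic annotation
#'
#' Assigns each piRNA locus exactly one category by precedence:
#' `RE_within_GENCODE` (overlaps both a repeat and a gene element), `RE_only`
#' (repeat only), `GENCODE_element` (gene only), `cluster_member` (overlaps a
#' called piRNA cluster but no other annotation, when `clusters` is given),
#' otherwise `unannotated`. Repeat-family proportions are reported for the
#' repeat-bearing categories.
#'
#' @param loci data.frame of piRNA loci (`chrom`, `start`, `end`; 0-based
#'   half-open) with optional `name`.
#' @param repeats Repeat annotation data.frame (`chrom`, `start`, `end`,
#'   `family`).
#' @param genes Gene-model annotation data.frame (`chrom`, `start`, `end`).
#' @param clusters Optional called-cluster data.frame (`chrom`, `start`,
#'   `end`).
#' @return List with `categories` (per-locus data.frame `name`, `category`,
#'   `family`), `category_proportions` and `family_proportions`.
#' @export
categorize_pirnas <- function(loci, repeats, genes, clusters = NULL) {
  assert_cols(loci, c("chrom", "start", "end"))
  assert_cols(repeats, c("chrom", "start", "end", "family"))
  assert_cols(genes, c("chrom", "start", "end"))
  ann_chroms <- unique(c(repeats$chrom, genes$chrom,
                         if (!is.null(clusters)) clusters$chrom))
  if (nrow(loci) && length(ann_chroms) &&
      !any(loci$chrom %in% ann_chroms))
    stopf("coordinate mismatch: no locus chromosome appears in the annotations")
  lg <- as_granges0(loci)
  ov_any <- function(ann) {
    if (is.null(ann) || nrow(ann) == 0L) return(rep(FALSE, nrow(loci)))
    GenomicRanges::countOverlaps(lg, as_granges0(ann),
                                 ignore.strand = TRUE) > 0L
  }
  in_re <- ov_any(repeats)
  in_gene <- ov_any(genes)
  in_cl <- ov_any(clusters)
  category <- ifelse(in_re & in_gene, "RE_within_GENCODE",
                     ifelse(in_re, "RE_only",
                            ifelse(in_gene, "GENCODE_element",
                                   ifelse(in_cl, "cluster_member",
                                          "unannotated"))))
  family <- rep(NA_character_, nrow(loci))
  if (any(in_re) && nrow(repeats)) {
    ov <- GenomicRanges::findOverlaps(lg, as_granges0(repeats),
                                      ignore.strand = TRUE)
    first <- !duplicated(S4Vectors::queryHits(ov))
    family[S4Vectors::queryHits(ov)[first]] <-
      repeats$family[S4Vectors::subjectHits(ov)[first]]
  }
  cats <- df(name = loci$name %||% as.character(seq_len(nrow(loci))),
             category = category, family = family)
  fam <- family[!is.na(family)]
  list(categories = cats,
       category_proportions = prop.table(table(category)),
       family_proportions = if (length(fam)) prop.table(table(fam)) else
         table(character(0)))
}

#' Predict piRNA targets on transcripts
#'
#' A target site exists where a transcript contains, within
#' `criteria` (defaults: <= 1 mismatch over >= 90% of the piRNA length),
#' either the piRNA sequence itself (sense homology) or its reverse
#' complement (antisense complementarity). Genes are the unit of reporting:
#' a gene is a target if any of its transcripts has a site; each distinct
#' targeting piRNA sequence is counted once per gene and its TPM summed
#' once.
#'
#' @param pirnas data.frame (`id`, `sequence`, optional `tpm`).
#' @param transcripts data.frame (`transcript_id`, `gene_id`, `sequence`).
#' @param criteria A [match_criteria()] object.
#' @return List with `sites` (per piRNA/transcript/orientation best hits)
#'   and `reports` (per-gene data.frame `gene_id`,
#'   `n_unique_targeting_pirnas`, `summed_targeting_tpm`, `sense_sites`,
#'   `antisense_sites`, `is_target`).
#' @export
predict_targets <- function(pirnas, transcripts, criteria = match_criteria()) {
  assert_cols(pirnas, c("id", "sequence"))
  assert_cols(transcripts, c("transcript_id", "gene_id", "sequence"))
  if (nrow(transcripts) == 0L) stopf("empty transcriptome")
  tpm <- pirnas$tpm %||% rep(0, nrow(pirnas))
  qs <- stats::setNames(pirnas$sequence, pirnas$id)
  ss <- stats::setNames(transcripts$sequence, transcripts$transcript_id)
  hits <- ungapped_hits(qs, ss, criteria)
  genes <- unique(transcripts$gene_id)
  if (nrow(hits) == 0L) {
    reports <- df(gene_id = genes, n_unique_targeting_pirnas = 0L,
                  summed_targeting_tpm = 0, sense_sites = 0L,
                  antisense_sites = 0L, is_target = FALSE)
    return(list(sites = hits, reports = reports))
  }
  hits$gene_id <- transcripts$gene_id[hits$sindex]
  pseq <- pirnas$sequence[match(hits$query, pirnas$id)]
  ptpm <- tpm[match(hits$query, pirnas$id)]
  reports <- do.call(rbind, lapply(genes, function(g) {
    hg <- hits[hits$gene_id == g, , drop = FALSE]
    sg <- pseq[hits$gene_id == g]
    # unique piRNA *sequences* per gene, counted and summed once each
    uniq <- !duplicated(sg)
    df(gene_id = g,
       n_unique_targeting_pirnas = sum(uniq),
       summed_targeting_tpm = sum(ptpm[hits$gene_id == g][uniq]),
       sense_sites = sum(hg$orientation == "sense"),
       antisense_sites = sum(hg$orientation == "antisense"),
       is_target = nrow(hg) > 0L)
  }))
  reports$is_target <- reports$n_unique_targeting_pirnas >= 1L
  list(sites = hits, reports = reports)
}

#' Summarize per-gene piRNA target loads
#'
#' @param reports Per-gene report data.frame from [predict_targets()],
#'   optionally augmented with `log2FoldChange` and `modulated` columns.
#' @return List of distribution summaries (max/median unique piRNAs and
#'   summed TPM per gene; modulated target/nontarget quadrant counts when
#'   modulation columns are present).
#' @export
target_load_summary <- function(reports) {
  assert_cols(reports, c("gene_id", "n_unique_targeting_pirnas",
                         "summed_targeting_tpm", "is_target"))
  if (nrow(reports) == 0L) stopf("no genes in report")
  out <- list(n_genes = nrow(reports),
              n_targets = sum(reports$is_target),
              max_unique_pirnas = max(reports$n_unique_targeting_pirnas),
              median_unique_pirnas =
                stats::median(reports$n_unique_targeting_pirnas),
              max_summed_tpm = max(reports$summed_targeting_tpm),
              median_summed_tpm = stats::median(reports$summed_targeting_tpm))
  if ("modulated" %in% names(reports)) {
    out$modulated_targets <- sum(reports$modulated & reports$is_target)
    out$modulated_nontargets <- sum(reports$modulated & !reports$is_target)
  }
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs. The p-value is
#' computed by exact enumeration over all assignments of the pooled sample
#' when `n1 + n2 <= 20` (valid under ties), otherwise by the asymptotic
#' Kolmogorov distribution with effective size `n1 n2 / (n1 + n2)`.
#'
#' @param x,y Numeric samples (e.g. log2 fold changes of target and
#'   nontarget genes).
#' @return List with `statistic` (D), `p.value` and `method`.
#' @export
ks_compare <- function(x, y) {
  if (!length(x) || !length(y)) stopf("empty sample")
  n1 <- length(x); n2 <- length(y)
  D <- ks_statistic(x, y)
  if (n1 + n2 <= 20L) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    ds <- apply(idx, 2L, function(i)
      ks_statistic(pooled[i], pooled[-i]))
    p <- mean(ds >= D - 1e-12)
    method <- "exact enumeration"
  } else {
    ne <- n1 * n2 / (n1 + n2)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    k <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
    method <- "asymptotic"
  }
  list(statistic = D, p.value = p, method = method)
}

# sup |ECDF1 - ECDF2| evaluated at the pooled distinct values
ks_statistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  F1 <- findInterval(v, sort(x)) / length(x)
  F2 <- findInterval(v, sort(y)) / length(y)
  max(abs(F1 - F2))
}

#' Spearman correlation between piRNA levels and target fold changes
#'
#' Rank (average ties), then Pearson; p-value from the t approximation.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho` and `p.value`.
#' @export
spearman_targets <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stopf("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant vector: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p.value = p)
}
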