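#' Identify piRNAs by annotated-reference matching
#'
#' A read qualifies as a piRNA iff it aligns to an annotated reference piRNA
#' with zero mismatches: identical to a reference, an exact substring of one,
#' or an exact superstring (the reference contained in the read). Matching is
#' sense-orientation only by default.
#'
#' @param reads Collapsed read data.frame (`sequence`, `count`, `sample`) or
#'   a character vector of sequences.
#' @param reference data.frame with columns `id`, `sequence` (piRBase-like).
#' @param orientations `"sense"` (default) or both orientations.
#' @return List with `matched` (subset of `reads`), `is_matched` (logical
#'   per unique input sequence, named) and `stats`.
#' @export
match_pirbase <- function(reads, reference, orientations = "sense") {
  if (is.character(reads)) reads <- df(sequence = reads, count = 1L,
                                       sample = "sample1")
  assert_cols(reads, c("sequence", "count", "sample"))
  assert_cols(reference, c("id", "sequence"))
  if (nrow(reference) == 0L) stopf("empty piRNA reference")
  uniq <- unique(toupper(reads$sequence))
  refs <- toupper(reference$sequence)
  matched <- stats::setNames(rep(FALSE, length(uniq)), uniq)
  for (ori in orientations) {
    q <- if (ori == "sense") uniq else revcomp(uniq)
    matched <- matched |
      contained_in(q, refs) |        # read inside a reference
      contains_any(q, refs)          # reference inside the read
  }
  is_m <- matched[toupper(reads$sequence)]
  out <- reads[is_m, , drop = FALSE]
  rownames(out) <- NULL
  log_stage("match_pirbase", nrow(reads), nrow(out),
            sprintf("(multiplicity %d -> %d)", sum(reads$count),
                    sum(out$count)))
  list(matched = out, is_matched = matched,
       stats = list(n_in = nrow(reads), n_matched = nrow(out),
                    multiplicity_matched = sum(out$count)))
}

# TRUE for each query occurring exactly (0 mismatches) inside any subject.
contained_in <- function(queries, subjects) {
  out <- rep(FALSE, length(queries))
  ok <- !grepl("N", queries, fixed = TRUE) & nzchar(queries)
  if (!any(ok) || !length(subjects)) return(out)
  sep <- max(nchar(queries)) + 10L
  superchr <- paste(subjects, collapse = strrep("N", sep))
  L <- nchar(queries)
  for (w in unique(L[ok])) {
    grp <- which(ok & L == w)
    lk <- kmer_lookup(kmer_index(superchr, w), queries[grp])
    out[grp[unique(lk$qi)]] <- TRUE
  }
  out
}

# TRUE for each query exactly containing any subject.
contains_any <- function(queries, subjects) {
  out <- rep(FALSE, length(queries))
  subjects <- subjects[!grepl("N", subjects, fixed = TRUE) & nzchar(subjects)]
  if (!length(subjects) || !length(queries)) return(out)
  sep <- max(nchar(subjects)) + 10L
  starts <- cumsum(c(1L, nchar(queries)[-length(queries)] + sep))
  superchr <- paste(queries, collapse = strrep("N", sep))
  L <- nchar(subjects)
  for (w in unique(L)) {
    lk <- kmer_lookup(kmer_index(superchr, w), subjects[L == w])
    if (length(lk$pos)) out[unique(findInterval(lk$pos, starts))] <- TRUE
  }
  out
}

#' Align reads to a genome (exact matching)
#'
#' Reports all zero-mismatch occurrences of each unique read sequence on both
#' strands, in deterministic (chrom, start) order, up to `cap` placements per
#' sequence (matching the published 100-alignment cap). Sequences with no
#' occurrence are dropped with a logged count; sequences containing `N`
#' cannot align exactly and are likewise dropped.
#'
#' @param reads Collapsed read data.frame or character vector.
#' @param genome Named character vector of chromosome sequences.
#' @param cap Maximum alignments kept per sequence.
#' @return data.frame (`sequence`, `chrom`, `start`, `end`, `strand`) with
#'   0-based half-open coordinates; attributes `n_unaligned` and `n_capped`.
#' @export
align_genome <- function(reads, genome, cap = 100L) {
  if (is.character(reads)) reads <- df(sequence = reads, count = 1L,
                                       sample = "sample1")
  assert_cols(reads, "sequence")
  stopifnot(is.character(genome), !is.null(names(genome)))
  uniq <- unique(toupper(reads$sequence))
  ok <- !grepl("N", uniq, fixed = TRUE)
  sep <- max(nchar(uniq)) + 10L
  superchr <- paste(toupper(genome), collapse = strrep("N", sep))
  chrom_starts <- cumsum(c(1L, nchar(genome)[-length(genome)] + sep))
  hits <- list()
  L <- nchar(uniq)
  for (w in unique(L[ok])) {
    grp <- which(ok & L == w)
    idx <- kmer_index(superchr, w)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") uniq[grp] else revcomp(uniq[grp])
      lk <- kmer_lookup(idx, q)
      if (!length(lk$qi)) next
      ci <- findInterval(lk$pos, chrom_starts)
      st <- lk$pos - chrom_starts[ci]          # 0-based within chromosome
      hits[[length(hits) + 1L]] <-
        df(sequence = uniq[grp[lk$qi]], chrom = names(genome)[ci],
           start = st, end = st + w, strand = strand)
    }
  }
  if (!length(hits)) {
    out <- df(sequence = character(0), chrom = character(0),
              start = integer(0), end = integer(0), strand = character(0))
    attr(out, "n_unaligned") <- length(uniq)
    attr(out, "n_capped") <- 0L
    return(out)
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$sequence, res$chrom, res$start, res$strand), ,
             drop = FALSE]
  # cap placements per sequence, keeping the first `cap` in sorted order
  r <- stats::ave(seq_len(nrow(res)), res$sequence, FUN = seq_along)
  n_capped <- length(unique(res$sequence[r > cap]))
  res <- res[r <= cap, , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$sequence), , drop = FALSE]
  rownames(res) <- NULL
  aligned <- unique(res$sequence)
  attr(res, "n_unaligned") <- length(uniq) - length(aligned)
  attr(res, "n_capped") <- n_capped
  log_stage("align_genome", length(uniq), length(aligned),
            sprintf("(placements=%d capped=%d)", nrow(res), n_capped))
  res
}

#' Call piRNA clusters by merging overlapping annotations
#'
#' Overlapping and book-ended (gap 0) piRNA loci are merged strand-agnostically
#' into clusters (the `mergeBed` preset behaviour); the cluster interval is
#' the union span. Output is sorted by (chrom, start) and clusters are
#' pairwise disjoint by construction.
#'
#' @param annotations data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name` for member bookkeeping.
#' @return data.frame (`id`, `chrom`, `start`, `end`, `length`, `n_members`,
#'   `members`).
#' @export
call_clusters <- function(annotations) {
  assert_cols(annotations, c("chrom", "start", "end"))
  if (nrow(annotations) == 0L)
    return(df(id = character(0), chrom = character(0), start = integer(0),
              end = integer(0), length = integer(0), n_members = integer(0),
              members = character(0)))
  gr <- as_granges0(annotations)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  nm <- annotations$name %||% as.character(seq_len(nrow(annotations)))
  members <- vapply(split(nm[S4Vectors::queryHits(ov)],
                          factor(S4Vectors::subjectHits(ov),
                                 levels = seq_along(merged))),
                    paste, "", collapse = ",")
  out <- granges_to_df0(merged)
  res <- df(chrom = out$chrom, start = out$start, end = out$end,
            length = out$end - out$start,
            n_members = as.integer(table(factor(S4Vectors::subjectHits(ov),
                                                levels = seq_along(merged)))),
            members = unname(members))
  # deterministic lexicographic (chrom, start) order, independent of the
  # order chromosomes first appear in the annotations
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  cbind(df(id = sprintf("cluster_%04d", seq_len(nrow(res)))), res)
}

#' Count read alignments fully contained in clusters
#'
#' Implements the `intersectBed -f 1` contract: an alignment is counted for a
#' cluster iff 100% of the alignment interval lies within the cluster
#' interval. Each placement of a multi-mapping read contributes its full read
#' multiplicity (alignment counting); `weighting = "fractional"` divides each
#' placement by the sequence's total number of placements instead.
#'
#' @param alignments data.frame from [align_genome()].
#' @param clusters data.frame from [call_clusters()] (must be disjoint).
#' @param reads Collapsed read data.frame carrying per-sample multiplicities.
#' @param weighting `"alignment"` (default) or `"fractional"`.
#' @return Numeric matrix clusters x samples of (weighted) read counts.
#' @export
count_cluster_reads <- function(alignments, clusters, reads,
                                weighting = c("alignment", "fractional")) {
  weighting <- match.arg(weighting)
  assert_cols(alignments, c("sequence", "chrom", "start", "end"))
  assert_cols(clusters, c("id", "chrom", "start", "end"))
  assert_cols(reads, c("sequence", "count", "sample"))
  cl_gr <- as_granges0(clusters)
  if (length(cl_gr) > 1L) {
    self <- GenomicRanges::findOverlaps(cl_gr, ignore.strand = TRUE,
                                        drop.self = TRUE)
    if (length(self) > 0L) stopf("clusters overlap: precondition violated")
  }
  samples <- sort(unique(reads$sample))
  counts <- matrix(0, nrow(clusters), length(samples),
                   dimnames = list(clusters$id, samples))
  if (nrow(alignments) == 0L) return(counts)
  al_gr <- as_granges0(alignments)
  ov <- GenomicRanges::findOverlaps(al_gr, cl_gr, type = "within",
                                    ignore.strand = TRUE)
  if (length(ov) == 0L) return(counts)
  hit <- df(sequence = alignments$sequence[S4Vectors::queryHits(ov)],
            cluster = clusters$id[S4Vectors::subjectHits(ov)])
  w <- rep(1, nrow(hit))
  if (weighting == "fractional") {
    nplace <- table(alignments$sequence)
    w <- 1 / as.numeric(nplace[hit$sequence])
  }
  # every (placement-in-cluster) x (sample multiplicity of that sequence)
  m <- merge(cbind(hit, weight = w), reads, by = "sequence")
  if (nrow(m) == 0L) return(counts)
  agg <- stats::aggregate(m$count * m$weight,
                          by = list(cluster = m$cluster, sample = m$sample),
                          FUN = sum)
  counts[cbind(agg$cluster, agg$sample)] <- agg$x
  counts
}

#' Summarize called clusters
#'
#' @param clusters data.frame from [call_clusters()].
#' @param counts Optional matrix from [count_cluster_reads()] for raw
#'   reads-per-cluster summaries.
#' @return List with `n_clusters`, length summaries, per-chromosome tallies
#'   and (if `counts` given) raw reads-per-cluster summaries.
#' @export
cluster_summary <- function(clusters, counts = NULL) {
  if (is.null(clusters) || nrow(clusters) == 0L) stopf("no clusters to summarize")
  out <- list(n_clusters = nrow(clusters),
              mean_length = mean(clusters$length),
              median_length = stats::median(clusters$length),
              max_length = max(clusters$length),
              per_chromosome = table(clusters$chrom))
  if (!is.null(counts)) {
    raw <- rowSums(counts)
    out$mean_reads_per_cluster <- mean(raw)
    out$max_reads_per_cluster <- max(raw)
  }
  out
}

#' Import ungapped alignments from a SAM file
#'
#' Minimal import path for externally produced alignments: only ungapped
#' (single `M` CIGAR) primary records are kept.
#'
#' @param path Path to a SAM file.
#' @return data.frame (`sequence`, `chrom`, `start`, `end`, `strand`) with
#'   0-based half-open coordinates.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(df(sequence = character(0), chrom = character(0),
              start = integer(0), end = integer(0), strand = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 11L
  if (any(bad)) stopf("malformed SAM record at line %d", which(bad)[1L])
  flag <- as.integer(vapply(f, `[`, "", 2L))
  chrom <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  cigar <- vapply(f, `[`, "", 6L)
  seqf <- toupper(vapply(f, `[`, "", 10L))
  keep <- chrom != "*" & grepl("^[0-9]+M$", cigar) &
    bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x4L) == 0L
  len <- as.integer(sub("M$", "", cigar[keep]))
  strand <- ifelse(bitwAnd(flag[keep], 0x10L) > 0L, "-", "+")
  seqs <- seqf[keep]
  # SAM stores the reverse-complement for minus-strand records
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  df(sequence = seqs, chrom = chrom[keep], start = pos[keep] - 1L,
     end = pos[keep] - 1L + len, strand = strand)
}
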