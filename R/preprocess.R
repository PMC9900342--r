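#' Trim 3' adapters and low-quality tails, then collapse reads
#'
#' Reimplements the standard small-RNA cleanup (`-m 25 -q 20` semantics):
#' first low-quality 3' tails are removed with the BWA/Cutadapt algorithm
#' (cut the suffix maximizing the sum of `min_quality - q`), then the longest
#' 3'-end match to a prefix of the adapter is removed (mismatch rate
#' `error_rate`, minimum overlap `min_overlap`, partial adapter at the read
#' end allowed), reads shorter than `min_length` are discarded, and survivors
#' are collapsed to unique (sequence, sample) pairs with multiplicities.
#'
#' @param records data.frame with a `sequence` column and optionally
#'   `quality_string` (phred+33) or a `quality` list-column, and a `sample`
#'   column; or a plain character vector of sequences.
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_quality Quality cutoff for 3' trimming.
#' @param min_length Minimum retained read length (reads with length
#'   `<= min_length - 1` are discarded; default keeps >= 25 nt).
#' @param error_rate Maximum adapter mismatch rate.
#' @param min_overlap Minimum adapter overlap considered.
#' @param sample Sample label used when `records` has no `sample` column.
#' @return List with `reads` (collapsed data.frame `sequence`, `count`,
#'   `sample`) and `stats` (record counts per stage).
#' @export
trim_reads <- function(records, adapter, min_quality = 20L, min_length = 25L,
                       error_rate = 0.10, min_overlap = 3L,
                       sample = "sample1") {
  if (!is_string(adapter) || !nzchar(adapter)) stopf("adapter must be non-empty")
  adapter <- toupper(adapter)
  if (is.character(records)) records <- df(sequence = records)
  assert_cols(records, "sequence")
  seqs <- toupper(records$sequence)
  samp <- if ("sample" %in% names(records)) records$sample else
    rep(sample, length(seqs))
  n_in <- length(seqs)

  qual <- NULL
  if ("quality_string" %in% names(records)) qual <- records$quality_string
  else if ("quality" %in% names(records))
    qual <- vapply(records$quality, function(x) intToUtf8(x + 33L), "")

  n_qtrim <- 0L
  if (!is.null(qual) && min_quality > 0L) {
    # only reads containing a base below the cutoff can be trimmed
    cut_char <- min_quality + 33L
    has_low <- grepl(sprintf("[\\x21-\\x%02x]", cut_char - 1L), qual,
                     perl = TRUE)
    idx <- which(has_low)
    n_qtrim <- length(idx)
    for (i in idx) {
      q <- utf8ToInt(qual[i]) - 33L
      d <- q - min_quality
      s <- rev(cumsum(rev(d)))         # s[i] = sum_{j >= i} (q - cutoff)
      if (min(s) < 0) {
        cut <- which.min(s)            # leftmost minimum: longest trim
        seqs[i] <- substr(seqs[i], 1L, cut - 1L)
      }
    }
  }

  # adapter trimming, grouped by read length; raw byte matrices keep the
  # mismatch counting in C
  alen <- nchar(adapter)
  araw <- charToRaw(adapter)
  lens <- nchar(seqs)
  n_atrim <- 0L
  for (L in sort(unique(lens[lens > 0L]), decreasing = TRUE)) {
    grp <- which(lens == L)
    m <- matrix(charToRaw(paste(seqs[grp], collapse = "")), nrow = L)
    best <- rep(NA_integer_, length(grp))
    unset <- rep(TRUE, length(grp))
    for (k in seq_len(L)) {
      w <- min(alen, L - k + 1L)
      if (w < min_overlap) break
      if (!any(unset)) break
      tol <- floor(error_rate * w)
      mm <- colSums(m[k:(k + w - 1L), unset, drop = FALSE] != araw[1:w])
      hit <- mm <= tol
      if (any(hit)) {
        ids <- which(unset)[hit]
        best[ids] <- k
        unset[ids] <- FALSE
      }
    }
    trimmed <- !is.na(best)
    n_atrim <- n_atrim + sum(trimmed)
    seqs[grp[trimmed]] <- substr(seqs[grp[trimmed]], 1L,
                                 best[trimmed] - 1L)
  }

  keep <- nchar(seqs) >= min_length
  n_short <- sum(!keep)
  seqs <- seqs[keep]; samp <- samp[keep]

  key <- paste0(samp, "\r", seqs)
  f <- factor(key)
  cnt <- tabulate(f, nbins = nlevels(f))
  parts <- strsplit(levels(f), "\r", fixed = TRUE)
  reads <- df(sequence = vapply(parts, `[`, "", 2L),
              count = cnt,
              sample = vapply(parts, `[`, "", 1L))
  reads <- reads[order(reads$sample, reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL

  stats <- list(n_input = n_in, n_quality_trimmed = n_qtrim,
                n_adapter_trimmed = n_atrim, n_discarded_short = n_short,
                n_retained = sum(keep), n_unique = nrow(reads))
  log_stage("trim_reads", n_in, stats$n_retained,
            sprintf("(unique=%d short=%d)", stats$n_unique, n_short))
  list(reads = reads, stats = stats)
}

#' Write collapsed reads as FASTA with multiplicity headers
#'
#' Uses the `>seq<i>_x<count>` header dialect common to collapsed small-RNA
#' FASTA files.
#'
#' @param reads Collapsed read data.frame (`sequence`, `count`, `sample`).
#' @param path Output path (one sample per file).
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  assert_cols(reads, c("sequence", "count"))
  if (length(unique(reads$sample %||% "s")) > 1L)
    stopf("write one sample per collapsed FASTA file")
  write_fasta(df(id = sprintf("seq%d_x%d", seq_len(nrow(reads)),
                              reads$count),
                 sequence = reads$sequence), path)
}

#' Read a collapsed-read FASTA (`>seq<i>_x<count>` dialect)
#'
#' @param path Input path.
#' @param sample Sample label to attach.
#' @return Collapsed read data.frame (`sequence`, `count`, `sample`).
#' @export
read_collapsed_fasta <- function(path, sample = "sample1") {
  x <- read_fasta(path)
  cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", x$id)))
  if (anyNA(cnt)) stopf("missing _x<count> multiplicity in header")
  df(sequence = x$sequence, count = cnt, sample = sample)
}

#' Remove reads matching known non-coding RNAs
#'
#' A read is removed iff there is an ungapped alignment of the read to some
#' reference, in either orientation by default, with query coverage,
#' identity and mismatch count within `criteria` (defaults 90 / 80 / 1, the
#' published decontamination settings). At most one best hit is recorded per
#' read; ties are broken by reference order.
#'
#' @param reads Collapsed read data.frame (`sequence`, `count`, `sample`) as
#'   produced by [trim_reads()], or a character vector.
#' @param references data.frame with columns `id`, `class`, `sequence`
#'   (class labels such as snoRNA, tRNA, miRNA_hairpin, miRNA_mature, rDNA).
#' @param criteria A [match_criteria()] object.
#' @return List with `retained` (read rows with no qualifying hit),
#'   `removed` (read rows plus `class`, `reference`, `identity`, `coverage`,
#'   `mismatches`) and `stats`.
#' @export
filter_ncrna <- function(reads, references, criteria = match_criteria()) {
  if (is.character(reads)) reads <- df(sequence = reads,
                                       count = 1L, sample = "sample1")
  assert_cols(reads, c("sequence", "count", "sample"))
  if (is.null(references) || nrow(references) == 0L) {
    warnf("empty ncRNA reference set: all reads retained")
    return(list(retained = reads,
                removed = cbind(reads[0, , drop = FALSE],
                                df(class = character(0),
                                   reference = character(0),
                                   identity = numeric(0),
                                   coverage = numeric(0),
                                   mismatches = integer(0))),
                stats = list(n_in = nrow(reads), n_removed = 0L)))
  }
  assert_cols(references, c("id", "class", "sequence"))
  uniq <- unique(reads$sequence)
  qs <- stats::setNames(uniq, uniq)
  ss <- stats::setNames(references$sequence, references$id)
  hits <- ungapped_hits(qs, ss, criteria, skip_exact_covered = TRUE)
  best <- NULL
  if (nrow(hits)) {
    ori_rank <- match(hits$orientation, c("sense", "antisense"))
    ord <- order(hits$query, -hits$identity, -hits$coverage, hits$sindex,
                 ori_rank)
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(hits$query), , drop = FALSE]
  }
  removed_seq <- if (is.null(best)) character(0) else best$query
  is_rm <- reads$sequence %in% removed_seq
  removed <- reads[is_rm, , drop = FALSE]
  if (nrow(removed)) {
    i <- match(removed$sequence, best$query)
    removed$class <- references$class[best$sindex[i]]
    removed$reference <- best$subject[i]
    removed$identity <- best$identity[i]
    removed$coverage <- best$coverage[i]
    removed$mismatches <- best$mismatches[i]
  } else {
    removed <- cbind(removed, df(class = character(0),
                                 reference = character(0),
                                 identity = numeric(0), coverage = numeric(0),
                                 mismatches = integer(0)))
  }
  retained <- reads[!is_rm, , drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  log_stage("filter_ncrna", nrow(reads), nrow(retained),
            sprintf("(removed=%d multiplicity=%d)", nrow(removed),
                    sum(removed$count)))
  list(retained = retained, removed = removed,
       stats = list(n_in = nrow(reads), n_removed = nrow(removed),
                    multiplicity_in = sum(reads$count),
                    multiplicity_removed = sum(removed$count)))
}
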