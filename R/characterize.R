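#' Multiplicity-weighted read length distribution
#'
#' @param reads Collapsed read data.frame (`sequence`, `count`) or character
#'   vector (counts of 1).
#' @return List with `freq` (named numeric vector of frequencies summing to
#'   1) and `mode` (the most frequent length).
#' @export
length_distribution <- function(reads) {
  if (is.character(reads))
    reads <- df(sequence = reads, count = rep(1L, length(reads)))
  assert_cols(reads, c("sequence", "count"))
  if (nrow(reads) == 0L) stopf("empty read set")
  lens <- nchar(reads$sequence)
  tab <- tapply(reads$count, lens, sum)
  freq <- as.numeric(tab) / sum(reads$count)
  names(freq) <- names(tab)
  list(freq = freq, mode = as.integer(names(freq)[which.max(freq)]))
}

#' 5' nucleotide bias
#'
#' Positional nucleotide frequencies over the first `n_positions` bases,
#' multiplicity-weighted; reports the 1U fraction (T at position 1 in DNA
#' space) and the 10A fraction used for secondary-piRNA classification.
#'
#' @param reads Collapsed read data.frame (`sequence`, `count`) or character
#'   vector.
#' @param n_positions Number of 5' positions profiled.
#' @return List with `matrix` (4 x n_positions frequency matrix, columns sum
#'   to 1), `u1_fraction` and `a10_fraction`.
#' @export
five_prime_bias <- function(reads, n_positions = 10L) {
  if (is.character(reads))
    reads <- df(sequence = reads, count = rep(1L, length(reads)))
  assert_cols(reads, c("sequence", "count"))
  if (nrow(reads) == 0L) stopf("empty read set")
  m <- matrix(0, 4L, n_positions, dimnames = list(c("A", "C", "G", "T"),
                                                  seq_len(n_positions)))
  seqs <- toupper(reads$sequence)
  for (p in seq_len(n_positions)) {
    b <- substr(seqs, p, p)
    has <- b %in% rownames(m)
    if (!any(has)) next
    t <- tapply(reads$count[has], b[has], sum)
    m[names(t), p] <- as.numeric(t)
    m[, p] <- m[, p] / sum(m[, p])
  }
  list(matrix = m, u1_fraction = m["T", 1L],
       a10_fraction = if (n_positions >= 10L) m["A", 10L] else NA_real_)
}

#' Assign cluster-contained reads with their genomic 5' positions
#'
#' Pairs aligned reads with the cluster that fully contains them (`-f 1`
#' contract) and records the strand-aware 5' terminus of each placement.
#' Rows are unique over (cluster, sequence, 5' position, strand); abundance
#' is deliberately not carried, since the distance analysis is defined over
#' unique sequences.
#'
#' @param alignments data.frame from [align_genome()].
#' @param clusters data.frame from [call_clusters()].
#' @return data.frame (`cluster`, `sequence`, `pos5`, `strand`).
#' @export
assign_cluster_reads <- function(alignments, clusters) {
  assert_cols(alignments, c("sequence", "chrom", "start", "end", "strand"))
  assert_cols(clusters, c("id", "chrom", "start", "end"))
  if (nrow(alignments) == 0L || nrow(clusters) == 0L)
    return(df(cluster = character(0), sequence = character(0),
              pos5 = integer(0), strand = character(0)))
  ov <- GenomicRanges::findOverlaps(as_granges0(alignments),
                                    as_granges0(clusters), type = "within",
                                    ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  out <- df(cluster = clusters$id[S4Vectors::subjectHits(ov)],
            sequence = alignments$sequence[qh],
            pos5 = ifelse(alignments$strand[qh] == "+",
                          alignments$start[qh], alignments$end[qh] - 1L),
            strand = alignments$strand[qh])
  unique(out)
}

#' Classify putative primary and secondary piRNAs
#'
#' Default `"signature"` rule uses the canonical biogenesis signatures:
#' primary = first base T (1U); secondary = tenth base A (10A) and first
#' base not T; reads with neither signature are excluded. The alternative
#' `"abundance"` rule labels the most abundant sequence at each 5' position
#' primary and the rest secondary.
#'
#' @param x data.frame with a `sequence` column (for the abundance rule also
#'   `pos5` and `count`).
#' @param rule `"signature"` (default) or `"abundance"`.
#' @return `x` with a `class` column (`primary`/`secondary`), excluded rows
#'   dropped; attribute `n_excluded`.
#' @export
classify_primary_secondary <- function(x, rule = c("signature", "abundance")) {
  rule <- match.arg(rule)
  assert_cols(x, "sequence")
  s <- toupper(x$sequence)
  if (rule == "signature") {
    is_p <- startsWith(s, "T")
    is_s <- !is_p & substr(s, 10L, 10L) == "A"
    cls <- ifelse(is_p, "primary", ifelse(is_s, "secondary", NA_character_))
  } else {
    assert_cols(x, c("pos5", "count"))
    cls <- rep("secondary", nrow(x))
    # one primary per 5' position: the most abundant sequence (ties by order)
    for (grp in split(seq_len(nrow(x)), x$pos5))
      cls[grp[which.max(x$count[grp])]] <- "primary"
  }
  out <- x[!is.na(cls), , drop = FALSE]
  out$class <- cls[!is.na(cls)]
  attr(out, "n_excluded") <- sum(is.na(cls))
  out
}

#' 5'-5' distance probability profile
#'
#' For every cluster, every same-strand (primary, secondary) pair of unique
#' sequences contributes the signed distance `secondary 5' - primary 5'`
#' within `+/-window`. Each cluster's histogram (over unique sequences,
#' abundance ignored) is normalized and the profile is aggregated as the
#' unweighted mean across contributing clusters, then smoothed by
#' [lowess_fit()] with span `span`.
#'
#' @param assigned Classified cluster reads: data.frame (`cluster`,
#'   `sequence`, `pos5`, `strand`, `class`) as produced by
#'   [assign_cluster_reads()] + [classify_primary_secondary()].
#' @param window Maximum absolute distance (nt).
#' @param span LOWESS span for the smoothed profile.
#' @param normalization `"histogram"` normalizes each cluster's histogram to
#'   sum 1 (default); `"diverse"` divides by the cluster's number of diverse
#'   (unique) sequences instead.
#' @return List with `profile` (data.frame `distance`, `probability`,
#'   `smoothed`) and `n_clusters_contributing`.
#' @export
distance_probability <- function(assigned, window = 200L, span = 0.1,
                                 normalization = c("histogram", "diverse")) {
  normalization <- match.arg(normalization)
  assert_cols(assigned, c("cluster", "sequence", "pos5", "strand", "class"))
  dists <- seq(-window, window)
  per_cluster <- list()
  for (cl in unique(assigned$cluster)) {
    sub <- assigned[assigned$cluster == cl, , drop = FALSE]
    sub <- unique(sub[, c("sequence", "pos5", "strand", "class")])
    h <- numeric(length(dists))
    for (str in unique(sub$strand)) {
      p <- sub$pos5[sub$class == "primary" & sub$strand == str]
      s <- sub$pos5[sub$class == "secondary" & sub$strand == str]
      if (!length(p) || !length(s)) next
      d <- as.vector(outer(s, p, "-"))
      d <- d[abs(d) <= window]
      if (length(d)) h <- h + tabulate(d + window + 1L,
                                       nbins = length(dists))
    }
    if (sum(h) == 0) next
    denom <- switch(normalization,
                    histogram = sum(h),
                    diverse = length(unique(sub$sequence)))
    per_cluster[[cl]] <- h / denom
  }
  if (!length(per_cluster)) {
    warnf("no qualifying primary/secondary pairs: empty distance profile")
    return(list(profile = df(distance = integer(0), probability = numeric(0),
                             smoothed = numeric(0)),
                n_clusters_contributing = 0L))
  }
  prob <- rowMeans(do.call(cbind, per_cluster))
  smoothed <- lowess_fit(dists, prob, span = span)
  list(profile = df(distance = dists, probability = prob,
                    smoothed = smoothed),
       n_clusters_contributing = length(per_cluster))
}

#' Locally weighted linear regression (LOWESS)
#'
#' Degree-1 LOWESS with tricube weights and no robustness iterations, the
#' smoother behind the distance-probability profile. At each point a
#' weighted least-squares line is fitted over the `ceiling(span * n)`
#' nearest neighbours (by x-distance) and evaluated at that point.
#'
#' @param x,y Numeric vectors of equal length (x need not be sorted).
#' @param span Fraction of points in each local window, in (0, 1].
#' @return Fitted values aligned with the input order.
#' @export
lowess_fit <- function(x, y, span = 0.1) {
  stopifnot(length(x) == length(y), span > 0, span <= 1)
  n <- length(x)
  if (n < 3L) stopf("lowess_fit needs at least 3 points")
  q <- ceiling(span * n)
  if (q < 2L) stopf("span x n < 2: cannot fit a local line")
  fit <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    dmax <- sort(d, partial = q)[q]
    if (dmax == 0) {
      w <- as.numeric(d == 0)
    } else {
      u <- d / dmax
      w <- ifelse(u < 1, (1 - u^3)^3, 0)
    }
    sw <- sum(w)
    xm <- sum(w * x) / sw
    ym <- sum(w * y) / sw
    sxx <- sum(w * (x - xm)^2)
    b <- if (sxx > 0) sum(w * (x - xm) * (y - ym)) / sxx else 0
    fit[i] <- ym + b * (x[i] - xm)
  }
  fit
}
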