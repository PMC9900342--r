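# Brute-force oracles, written as literal enumerations of the definitions.
# They share no code with the package implementations they check.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

# Ungapped-alignment existence by scanning every diagonal and every window.
oracle_hit_exists <- function(q, refs, max_mm = 1L, min_id = 80,
                              min_qcov = 90,
                              orientations = c("sense", "antisense")) {
  L <- nchar(q)
  wmin <- ceiling(min_qcov / 100 * L)
  for (ori in orientations) {
    qq <- if (ori == "sense") q else oracle_revcomp(q)
    qv <- utf8ToInt(qq)
    for (ref in refs) {
      sv <- utf8ToInt(ref)
      S <- length(sv)
      for (o in seq.int(2L - L, S)) {
        i1 <- max(1L, 2L - o); i2 <- min(L, S - o + 1L)
        n <- i2 - i1 + 1L
        if (n < wmin) next
        a_q <- qv[i1:i2]; a_s <- sv[(o + i1 - 1L):(o + i2 - 1L)]
        mm <- a_q != a_s | a_q == 78L | a_s == 78L   # 78 == "N"
        for (len in wmin:n) {
          for (a in seq_len(n - len + 1L)) {
            cnt <- sum(mm[a:(a + len - 1L)])
            if (cnt <= max_mm && (len - cnt) / len * 100 >= min_id)
              return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

# Zero-mismatch reference matching via the regex engine.
oracle_pirbase_match <- function(read, refs) {
  any(vapply(refs, function(r) grepl(read, r, fixed = TRUE) ||
               grepl(r, read, fixed = TRUE), TRUE))
}

# All exact genome placements of a read via gregexpr, both strands.
oracle_align <- function(read, genome) {
  out <- NULL
  w <- nchar(read)
  for (ch in names(genome)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else oracle_revcomp(read)
      # gregexpr misses overlapping hits; rescan from each hit + 1
      pos <- integer(0); from <- 1L
      repeat {
        p <- regexpr(q, substring(genome[[ch]], from), fixed = TRUE)
        if (p < 0) break
        pos <- c(pos, from + p - 1L)
        from <- from + p
      }
      if (length(pos))
        out <- rbind(out, data.frame(sequence = read, chrom = ch,
                                     start = pos - 1L, end = pos - 1L + w,
                                     strand = strand,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

# Interval merging by marking occupied bases (book-ended intervals become
# adjacent marks, hence merge, exactly the mergeBed preset).
oracle_merge <- function(intervals) {
  out <- NULL
  for (ch in sort(unique(intervals$chrom))) {
    sub <- intervals[intervals$chrom == ch, ]
    occupied <- rep(FALSE, max(sub$end))
    for (i in seq_len(nrow(sub)))
      occupied[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    r <- rle(occupied)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values))
      out <- rbind(out, data.frame(chrom = ch, start = starts[j] - 1L,
                                   end = ends[j], stringsAsFactors = FALSE))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# -f 1 containment counting by triple loop.
oracle_count <- function(alignments, clusters, reads) {
  samples <- sort(unique(reads$sample))
  counts <- matrix(0, nrow(clusters), length(samples),
                   dimnames = list(clusters$id, samples))
  for (i in seq_len(nrow(alignments))) {
    for (j in seq_len(nrow(clusters))) {
      if (alignments$chrom[i] == clusters$chrom[j] &&
          alignments$start[i] >= clusters$start[j] &&
          alignments$end[i] <= clusters$end[j]) {
        rr <- reads[reads$sequence == alignments$sequence[i], ]
        for (k in seq_len(nrow(rr)))
          counts[j, rr$sample[k]] <- counts[j, rr$sample[k]] + rr$count[k]
      }
    }
  }
  counts
}

# Per-point weighted least squares via lm(), the LOWESS oracle.
oracle_lowess_point <- function(x, y, i, span) {
  n <- length(x)
  q <- ceiling(span * n)
  d <- abs(x - x[i])
  dmax <- sort(d)[q]
  w <- ifelse(d < dmax, (1 - (d / dmax)^3)^3, 0)
  if (dmax == 0) w <- as.numeric(d == 0)
  fit <- stats::lm(y ~ x, weights = w)
  unname(stats::predict(fit, data.frame(x = x[i])))
}

# Exact KS p-value by enumerating every labelling with combn + ecdf().
oracle_ks_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  v <- sort(unique(pooled))
  dstat <- function(a, b) max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
  obs <- dstat(x, y)
  labs <- utils::combn(length(pooled), n1)
  ds <- apply(labs, 2L, function(i) dstat(pooled[i], pooled[-i]))
  mean(ds >= obs - 1e-12)
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), "")
}

# Adjusted Rand index for the planted-partition k-means check.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
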