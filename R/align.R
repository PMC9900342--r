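#' Match criteria for ungapped sequence comparison
#'
#' The criteria used both for ncRNA decontamination and for in-silico target
#' assignment. Defaults are the published BLASTN settings: identity >= 80%,
#' at most 1 mismatch, query coverage >= 90%, one best hit reported.
#'
#' @param min_identity Minimum percent identity of the aligned window.
#' @param max_mismatches Maximum mismatches in the aligned window. `N` bases
#'   always count as mismatches.
#' @param min_query_coverage Minimum percent of the query covered by the
#'   aligned window.
#' @param max_hits_reported Hits recorded per query (ties broken by
#'   reference order).
#' @param orientations Orientations searched: `sense` (query as given),
#'   `antisense` (reverse complement of the query).
#' @return List of class `match_criteria`.
#' @export
match_criteria <- function(min_identity = 80, max_mismatches = 1L,
                           min_query_coverage = 90, max_hits_reported = 1L,
                           orientations = c("sense", "antisense")) {
  stopifnot(min_identity > 0, min_identity <= 100,
            max_mismatches >= 0,
            min_query_coverage > 0, min_query_coverage <= 100,
            all(orientations %in% c("sense", "antisense")))
  structure(list(min_identity = min_identity,
                 max_mismatches = as.integer(max_mismatches),
                 min_query_coverage = min_query_coverage,
                 max_hits_reported = as.integer(max_hits_reported),
                 orientations = orientations),
            class = "match_criteria")
}

# Best qualifying window on one diagonal. mm: logical mismatch vector along
# the overlap; wmin: minimum window length; m: max mismatches; idmin: minimum
# percent identity. Returns list(len, mm, a) for the longest qualifying
# window (fewest mismatches among those), or NULL.
window_scan <- function(mm, wmin, m, idmin) {
  n <- length(mm)
  if (n < wmin) return(NULL)
  cs <- c(0L, cumsum(mm))
  for (len in n:wmin) {
    a <- seq_len(n - len + 1L)
    cnt <- cs[a + len] - cs[a]
    ok <- cnt <= m & (len - cnt) / len * 100 >= idmin
    if (any(ok)) {
      best <- which(ok)[which.min(cnt[ok])]
      return(list(len = len, mm = cnt[best], a = a[best]))
    }
  }
  NULL
}

# Ungapped alignment of queries against subjects: a hit exists where some
# query window of length >= min_query_coverage% of the query aligns to a
# subject with <= max_mismatches mismatches and >= min_identity% identity.
#
# Strategy per orientation:
#   1. exact full-length occurrences via Biostrings PDict (these are
#      unbeatable hits: coverage 100, identity 100, 0 mismatches);
#   2. seed-and-verify for mismatched/partial hits: every qualifying window
#      contains an exact run of >= ceil((wmin - m)/(m + 1)) bases
#      (pigeonhole), so exact k-mer seeds against a hashed subject k-mer
#      index enumerate all candidate diagonals, which are then verified;
#   3. queries containing N, or whose pigeonhole bound is uninformative
#      (< 6), fall back to scanning every diagonal.
#
# Returns one row per (query, subject, orientation): the longest qualifying
# window with its mismatch count, coverage and identity, plus the 0-based
# subject start of the window.
ungapped_hits <- function(queries, subjects, criteria = match_criteria(),
                          skip_exact_covered = FALSE) {
  qn <- names(queries) %||% as.character(seq_along(queries))
  sn <- names(subjects) %||% as.character(seq_along(subjects))
  queries <- toupper(unname(queries)); subjects <- toupper(unname(subjects))
  empty <- df(query = character(0), subject = character(0),
              orientation = character(0), mismatches = integer(0),
              coverage = numeric(0), identity = numeric(0),
              sstart = integer(0), qindex = integer(0), sindex = integer(0))
  if (!length(queries) || !length(subjects)) return(empty)
  m <- criteria$max_mismatches
  idmin <- criteria$min_identity
  qcov <- criteria$min_query_coverage

  slen <- nchar(subjects)
  sep <- max(nchar(queries), 40L) + 10L
  superchr <- paste(subjects, collapse = strrep("N", sep))
  starts <- cumsum(c(1L, slen[-length(slen)] + sep))  # 1-based per subject
  sints <- lapply(subjects, seq_ints)
  NCODE <- utf8ToInt("N")

  out <- list()
  for (ori in criteria$orientations) {
    qseq <- if (ori == "sense") queries else revcomp(queries)
    L <- nchar(qseq)
    wmin <- ceiling(qcov / 100 * L)
    kq <- ceiling((wmin - m) / (m + 1L))
    has_n <- grepl("N", qseq, fixed = TRUE)
    qints <- NULL  # built lazily for verification

    # ---- exact full-length pass: emit finished hit rows -----------------
    idx_exact <- which(!has_n)
    exact_q <- integer(0)
    for (w in unique(L[idx_exact])) {
      grp <- idx_exact[L[idx_exact] == w]
      lk <- kmer_lookup(kmer_index(superchr, w), qseq[grp])
      if (!length(lk$qi)) next
      qi <- grp[lk$qi]
      sj <- findInterval(lk$pos, starts)
      out[[length(out) + 1L]] <-
        df(query = qn[qi], subject = sn[sj], orientation = ori,
           mismatches = 0L, coverage = 100, identity = 100,
           sstart = lk$pos - starts[sj], qindex = qi, sindex = sj)
      exact_q <- c(exact_q, unique(qi))
    }

    # ---- seed pass ------------------------------------------------------
    seed_idx <- which(!has_n & kq >= 6L)
    if (skip_exact_covered) seed_idx <- setdiff(seed_idx, exact_q)
    cand <- NULL
    if (length(seed_idx)) {
      k <- max(6L, min(28L, min(kq[seed_idx])))
      sidx <- kmer_index(superchr, k)
      n_off <- L[seed_idx] - k + 1L
      seed_qi <- rep(seed_idx, n_off)
      seed_off <- sequence(n_off)
      seeds <- substring(qseq[seed_qi], seed_off, seed_off + k - 1L)
      lk <- kmer_lookup(sidx, seeds)
      if (length(lk$qi)) {
        qi <- seed_qi[lk$qi]
        off <- seed_off[lk$qi]
        sj <- findInterval(lk$pos, starts)
        cand <- cbind(qi = qi, sj = sj,
                      o = lk$pos - starts[sj] + 1L - off + 1L)
      }
    }

    # ---- brute-force diagonals for queries the seed bound cannot serve --
    brute_idx <- which(has_n | kq < 6L)
    if (skip_exact_covered) brute_idx <- setdiff(brute_idx, exact_q)
    if (length(brute_idx)) {
      bl <- lapply(brute_idx, function(qi)
        do.call(rbind, lapply(seq_along(subjects), function(sj)
          cbind(qi = qi, sj = sj, o = seq.int(2L - L[qi], slen[sj])))))
      cand <- rbind(cand, do.call(rbind, bl))
    }

    if (is.null(cand) || nrow(cand) == 0L) next
    cand <- unique(cand)
    # drop candidates that merely re-find an exact full-length hit
    if (length(exact_q) && skip_exact_covered)
      cand <- cand[!(cand[, "qi"] %in% exact_q), , drop = FALSE]
    if (nrow(cand) == 0L) next

    qints <- lapply(qseq, seq_ints)
    acc <- matrix(NA_real_, nrow(cand), 5L)  # mm, cov, id, sstart, keep
    for (r in seq_len(nrow(cand))) {
      qi <- cand[r, "qi"]; sj <- cand[r, "sj"]; o <- cand[r, "o"]
      Lq <- L[qi]; S <- slen[sj]
      i1 <- max(1L, 2L - o); i2 <- min(Lq, S - o + 1L)
      if (i2 - i1 + 1L < wmin[qi]) next
      qv <- qints[[qi]][i1:i2]
      sv <- sints[[sj]][(o + i1 - 1L):(o + i2 - 1L)]
      mmv <- qv != sv | qv == NCODE | sv == NCODE
      wb <- window_scan(mmv, wmin[qi], m, idmin)
      if (is.null(wb)) next
      acc[r, ] <- c(wb$mm, wb$len / Lq * 100, (wb$len - wb$mm) / wb$len * 100,
                    (o + i1 - 1L + wb$a - 1L) - 1L, 1)
    }
    ok <- which(!is.na(acc[, 5L]))
    if (length(ok))
      out[[length(out) + 1L]] <-
        df(query = qn[cand[ok, "qi"]], subject = sn[cand[ok, "sj"]],
           orientation = ori, mismatches = as.integer(acc[ok, 1L]),
           coverage = acc[ok, 2L], identity = acc[ok, 3L],
           sstart = as.integer(acc[ok, 4L]),
           qindex = cand[ok, "qi"], sindex = cand[ok, "sj"])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # best row per (query, subject, orientation)
  key <- paste(res$qindex, res$sindex, res$orientation)
  ord <- order(key, -res$identity, -res$coverage, res$sindex)
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(key[ord]), , drop = FALSE]
  rownames(res) <- NULL
  res
}
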