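# Internal helpers shared across modules.

# Reverse complement for plain character vectors (ACGTN).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer codes of a single sequence; N (or any non-ACGT) never equals ACGT,
# so `!=` on these codes counts N as a mismatch, as required.
seq_ints <- function(s) utf8ToInt(s)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Stage logging: every pipeline stage reports its input/output record counts so
# that runs can be reconciled count-by-count.
log_stage <- function(stage, n_in, n_out, extra = "") {
  message(sprintf("[%s] in=%d out=%d %s", stage, n_in, n_out, extra))
  invisible(list(stage = stage, n_in = n_in, n_out = n_out))
}

# data.frame without the usual surprises
df <- function(...) data.frame(..., stringsAsFactors = FALSE)

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(x)
}

# Exact-substring index: all width-k windows of `superchr`, radix-sorted so
# every occurrence list is a contiguous run. Lookup is a single hashed
# match() call. Windows containing N are dropped (N never matches exactly).
kmer_index <- function(superchr, k) {
  npos <- nchar(superchr) - k + 1L
  if (npos < 1L) return(NULL)
  at <- seq_len(npos)
  sk <- substring(superchr, at, at + k - 1L)
  keep <- !grepl("N", sk, fixed = TRUE)
  pos <- which(keep); sk <- sk[keep]
  if (!length(sk)) return(NULL)
  o <- order(sk, method = "radix")
  sk <- sk[o]; pos <- pos[o]
  new_run <- c(TRUE, sk[-1L] != sk[-length(sk)])
  ufirst <- which(new_run)
  list(u = sk[new_run], ufirst = ufirst,
       ucnt = diff(c(ufirst, length(sk) + 1L)), pos = pos)
}

# All positions (1-based, in the indexed superstring) of each query;
# returns list(qi = query index per hit, pos = position per hit).
kmer_lookup <- function(idx, q) {
  if (is.null(idx)) return(list(qi = integer(0), pos = integer(0)))
  m <- match(q, idx$u)
  hit <- which(!is.na(m))
  if (!length(hit)) return(list(qi = integer(0), pos = integer(0)))
  mm <- m[hit]
  reps <- idx$ucnt[mm]
  list(qi = rep(hit, reps),
       pos = idx$pos[sequence(reps, from = idx$ufirst[mm])])
}

# GRanges from a 0-based half-open data.frame (chrom/start/end[/strand]).
# All coordinates in this package are 0-based half-open (BED convention);
# GRanges is 1-based closed, hence start + 1.
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = strand)
}

# Back from GRanges to 0-based half-open columns.
granges_to_df0 <- function(gr) {
  df(chrom  = as.character(GenomicRanges::seqnames(gr)),
     start  = GenomicRanges::start(gr) - 1L,
     end    = GenomicRanges::end(gr),
     strand = as.character(GenomicRanges::strand(gr)))
}
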