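#' Read a FASTA file
#'
#' Minimal strict FASTA reader. Multi-line sequences are concatenated, case is
#' folded to upper, and records are returned in file order. The parser is
#' deliberately strict: a sequence line containing characters outside
#' `A,C,G,T,N` aborts with an error naming the offending line.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A data.frame with columns `id`, `sequence` and `description`
#'   (text after the first whitespace in the header, `NA` if absent).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(df(id = character(0), sequence = character(0),
              description = character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stopf("malformed FASTA: line %d does not start with '>'", lineno[1L])
  seq_lines <- toupper(lines[!is_hdr])
  bad <- grepl("[^ACGTN]", seq_lines)
  if (any(bad)) {
    first <- which(bad)[1L]
    stopf("illegal character in sequence at line %d",
          lineno[!is_hdr][first])
  }
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(seq_lines, grp[!is_hdr]), paste, "", collapse = "")
  out <- character(max(grp))
  out[as.integer(names(seqs))] <- seqs
  if (any(out == ""))
    stopf("malformed FASTA: record '%s' has an empty sequence",
          headers[which(out == "")[1L]])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers),
                 NA_character_)
  df(id = id, sequence = out, description = desc)
}

#' Write sequences to FASTA
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  assert_cols(records, c("id", "sequence"))
  hdr <- paste0(">", records$id)
  if ("description" %in% names(records)) {
    has <- !is.na(records$description) & nzchar(records$description)
    hdr[has] <- paste(hdr[has], records$description[has])
  }
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    starts <- seq(1L, nchar(s), by = width)
    paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
          collapse = "\n")
  }
  body <- vapply(records$sequence, wrap, "", USE.NAMES = FALSE)
  writeLines(paste(hdr, body, sep = "\n"), path)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path Path to an uncompressed 4-line-record FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `description`, and a
#'   list-column `quality` of integer phred scores.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    out <- df(id = character(0), sequence = character(0),
              description = character(0))
    out$quality <- list()
    return(out)
  }
  if (length(lines) %% 4L != 0L)
    stopf("truncated FASTQ record: %d lines is not a multiple of 4",
          length(lines))
  ids  <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@")))
    stopf("malformed FASTQ header at record %d", which(!startsWith(ids, "@"))[1L])
  if (!all(startsWith(plus, "+")))
    stopf("malformed FASTQ separator at record %d", which(!startsWith(plus, "+"))[1L])
  if (any(nchar(seqs) != nchar(qual)))
    stopf("sequence/quality length mismatch at record %d",
          which(nchar(seqs) != nchar(qual))[1L])
  hdr <- sub("^@", "", ids)
  out <- df(id = sub("\\s.*$", "", hdr),
            sequence = seqs,
            description = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr),
                                 NA_character_))
  out$quality <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  out
}

#' Write reads to FASTQ (phred+33)
#'
#' @param records data.frame with `id`, `sequence` and a `quality` list-column
#'   of integer phred scores (or a `quality_string` character column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  assert_cols(records, c("id", "sequence"))
  q <- if ("quality_string" %in% names(records)) {
    records$quality_string
  } else {
    vapply(records$quality, function(x) intToUtf8(x + 33L), "")
  }
  writeLines(paste0("@", records$id, "\n", records$sequence, "\n+\n", q), path)
  invisible(path)
}

#' Read a BED file (BED6 dialect)
#'
#' Coordinates are kept exactly as in BED: 0-based half-open. Missing strand
#' defaults to `+`.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(x) < 3L) stopf("BED file must have >= 3 columns")
  out <- df(chrom = as.character(x[[1L]]),
            start = as.integer(x[[2L]]),
            end   = as.integer(x[[3L]]),
            name  = if (ncol(x) >= 4L) as.character(x[[4L]]) else ".",
            score = if (ncol(x) >= 5L) suppressWarnings(as.numeric(x[[5L]])) else 0,
            strand = if (ncol(x) >= 6L) as.character(x[[6L]]) else "+")
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stopf("non-numeric BED coordinates")
  if (any(out$start < 0L)) stopf("negative BED coordinate at row %d",
                                 which(out$start < 0L)[1L])
  if (any(out$start >= out$end))
    stopf("empty or inverted BED interval at row %d (start >= end)",
          which(out$start >= out$end)[1L])
  if (!all(out$strand %in% c("+", "-")))
    stopf("invalid strand at row %d", which(!out$strand %in% c("+", "-"))[1L])
  out
}

#' Write intervals to BED6
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  assert_cols(x, c("chrom", "start", "end"))
  out <- df(chrom = x$chrom, start = x$start, end = x$end,
            name = x$name %||% ".", score = x$score %||% 0,
            strand = x$strand %||% "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a numeric feature-by-sample matrix from TSV
#'
#' First column holds feature ids, header row holds sample ids. Values must be
#' non-negative numbers.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) stopf("ragged rows in matrix file")
  x <- utils::read.delim(path, header = TRUE, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x)
  if (!is.numeric(m)) stopf("non-numeric cells in matrix file")
  if (anyNA(m)) stopf("missing values in matrix file")
  if (any(m < 0)) stopf("negative values in matrix file")
  m
}

#' Write a numeric matrix to TSV
#'
#' Values are serialized with 15 significant digits, which round-trips doubles
#' well below the package-wide 1e-9 tolerance.
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param feature_col Name of the leading feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, feature_col = "feature") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- df(feature = rownames(m))
  names(out) <- feature_col
  vals <- as.data.frame(m, check.names = FALSE)
  for (j in seq_along(vals)) vals[[j]] <- format(vals[[j]], digits = 15,
                                                 trim = TRUE,
                                                 scientific = FALSE)
  utils::write.table(cbind(out, vals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
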