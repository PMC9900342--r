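#' Normalize counts to transcripts per million
#'
#' Small-RNA mode (no lengths): each column is scaled to sum 1e6. Transcript
#' mode: counts are divided by feature length first, then scaled per
#' million.
#'
#' @param counts Non-negative feature x sample matrix.
#' @param lengths Optional positive feature lengths (transcript mode).
#' @return TPM matrix; every column sums to 1e6.
#' @export
tpm_normalize <- function(counts, lengths = NULL) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stopf("negative counts")
  if (any(colSums(counts) == 0)) stopf("all-zero column: cannot normalize")
  x <- counts
  if (!is.null(lengths)) {
    stopifnot(length(lengths) == nrow(counts))
    if (any(lengths <= 0)) stopf("non-positive feature length")
    x <- counts / lengths
  }
  sweep(x, 2L, colSums(x), "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' The DESeq-style normalization: per-sample median of count ratios to the
#' per-feature geometric mean; features with any zero count (zero geometric
#' mean) are excluded from the median.
#'
#' @param counts Feature x sample count matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) stopf("no feature with all-positive counts")
  apply(counts, 2L, function(col) exp(stats::median(log(col[use]) -
                                                      loggeo[use])))
}

#' Differential feature analysis (negative-binomial surrogate)
#'
#' A documented surrogate for the DESeq2/edgeR steps: median-of-ratios size
#' factors, per-feature method-of-moments dispersion pooled as the mean
#' within up to 10 equal-occupancy baseline-mean bins, a Wald test on the
#' log2 fold change of normalized means referred to a t distribution whose
#' degrees of freedom reflect the dispersion-pooling information
#' (`occupancy x (nA + nB - 2) / 2`), and Benjamini-Hochberg adjustment.
#' A feature is called `up` iff padj <= `padj_threshold` and log2FC >=
#' `lfc_threshold`, `down` with log2FC <= -`lfc_threshold`.
#'
#' @param counts Feature x sample count matrix.
#' @param conditions Condition label per sample (exactly two levels).
#' @param padj_threshold,lfc_threshold Published call thresholds
#'   (0.05 and 1).
#' @param pseudocount Added to normalized group means before taking logs.
#' @return data.frame (`feature`, `baseMean`, `log2FoldChange`, `pvalue`,
#'   `padj`, `call`).
#' @export
differential_features <- function(counts, conditions, padj_threshold = 0.05,
                                  lfc_threshold = 1, pseudocount = 1) {
  stopifnot(is.matrix(counts), length(conditions) == ncol(counts))
  lev <- unique(conditions)
  if (length(lev) != 2L) stopf("exactly two conditions required")
  nA <- sum(conditions == lev[1L]); nB <- sum(conditions == lev[2L])
  if (nA < 2L || nB < 2L) stopf("each condition needs >= 2 samples")
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  A <- norm[, conditions == lev[1L], drop = FALSE]
  B <- norm[, conditions == lev[2L], drop = FALSE]
  muA <- rowMeans(A); muB <- rowMeans(B)
  baseMean <- rowMeans(norm)

  # method-of-moments dispersion per feature, pooled within mean bins
  varA <- apply(A, 1L, stats::var); varB <- apply(B, 1L, stats::var)
  pooled_var <- ((nA - 1L) * varA + (nB - 1L) * varB) / (nA + nB - 2L)
  mu_bar <- (muA * nA + muB * nB) / (nA + nB)
  disp_raw <- pmax(0, (pooled_var - mu_bar) / mu_bar^2)
  # equal-occupancy bins on the baseline mean, so every feature's dispersion
  # is pooled over a comparable number of neighbours
  n_bins <- max(1L, min(10L, nrow(counts) %/% 20L))
  qs <- unique(stats::quantile(baseMean, probs = seq(0, 1,
                                                     length.out = n_bins + 1L)))
  bin <- cut(baseMean, breaks = qs, include.lowest = TRUE)
  # bin MEAN, not median: per-feature moment estimates are right-skewed at
  # small n, so the median is biased low and anti-conservative
  disp <- stats::ave(disp_raw, bin, FUN = function(v) mean(v, na.rm = TRUE))
  disp[!is.finite(disp)] <- mean(disp_raw, na.rm = TRUE)

  log2fc <- log2((muB + pseudocount) / (muA + pseudocount))
  # delta-method variance of log2 of an NB group mean: (1/mu + alpha)/n
  se <- sqrt((1 / (muA + pseudocount) + disp) / nA +
               (1 / (muB + pseudocount) + disp) / nB) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  # t reference: the pooled dispersion carries roughly
  # occupancy x (nA + nB - 2) degrees of freedom; halved as a conservative
  # allowance for the per-feature mean estimates entering the SE. A plain
  # normal reference is measurably anti-conservative in the far tail here.
  occupancy <- as.numeric(table(bin)[bin])
  occupancy[is.na(occupancy)] <- 1
  df_t <- pmax(nA + nB - 2, occupancy * (nA + nB - 2) / 2)
  pvalue <- 2 * stats::pt(-abs(z), df_t)
  padj <- stats::p.adjust(pvalue, method = "BH")
  call <- ifelse(padj <= padj_threshold & log2fc >= lfc_threshold, "up",
                 ifelse(padj <= padj_threshold & log2fc <= -lfc_threshold,
                        "down", "unchanged"))
  df(feature = rownames(counts) %||% as.character(seq_len(nrow(counts))),
     baseMean = baseMean, log2FoldChange = log2fc, pvalue = pvalue,
     padj = padj, call = call)
}

#' Scaled-MAD outlier filter
#'
#' Removes values more than `multiplier` scaled MADs
#' (`1.4826 * median(|x - median(x)|)`) from the centre; the inequality is
#' strict, so a value at exactly `multiplier` scaled MADs is retained.
#' Median-centering is the default (the behaviour of the MATLAB outlier
#' tooling this rule reproduces); `center = "mean"` measures distances from
#' the mean instead. When the scaled MAD is zero, any nonzero deviation from
#' the centre is removed.
#'
#' @param x Numeric vector of replicate values for one feature.
#' @param multiplier MAD multiplier (default 3).
#' @param center `"median"` (default) or `"mean"`.
#' @param min_values Features retaining fewer than this many values are
#'   flagged as excluded from downstream testing.
#' @return List with `keep` (logical), `values` (retained values) and
#'   `excluded` (TRUE if fewer than `min_values` survive).
#' @export
mad_outlier_filter <- function(x, multiplier = 3, center = c("median", "mean"),
                               min_values = 4L) {
  center <- match.arg(center)
  stopifnot(is.numeric(x))
  smad <- 1.4826 * stats::median(abs(x - stats::median(x)))
  ctr <- if (center == "median") stats::median(x) else mean(x)
  dev <- abs(x - ctr)
  keep <- if (smad == 0) dev == 0 else dev <= multiplier * smad
  list(keep = keep, values = x[keep], excluded = sum(keep) < min_values)
}

#' Per-gene one-way ANOVA
#'
#' One-way ANOVA across condition groups for each feature row; in the
#' two-group case the F statistic equals the squared pooled t statistic.
#' Degenerate rows (zero within-group variance and equal means) get p = 1.
#'
#' @param values Feature x sample matrix (e.g. MAD-filtered TPM; NA allowed
#'   for removed values).
#' @param conditions Condition label per column.
#' @param alpha Significance threshold (p <= alpha).
#' @return data.frame (`feature`, `F`, `pvalue`, `significant`).
#' @export
per_gene_test <- function(values, conditions, alpha = 0.05) {
  stopifnot(is.matrix(values), length(conditions) == ncol(values))
  if (length(unique(conditions)) < 2L) stopf("need >= 2 groups")
  res <- t(apply(values, 1L, function(v) {
    ok <- !is.na(v)
    g <- factor(conditions[ok]); v <- v[ok]
    if (nlevels(g) < 2L || any(table(g) < 2L)) return(c(NA_real_, NA_real_))
    gm <- tapply(v, g, mean)
    n <- tapply(v, g, length)
    ssb <- sum(n * (gm - mean(v))^2)
    ssw <- sum((v - gm[g])^2)
    df1 <- nlevels(g) - 1L
    df2 <- length(v) - nlevels(g)
    if (ssw == 0) {
      if (ssb == 0) return(c(0, 1))  # degenerate: constant data
      return(c(Inf, 0))
    }
    f <- (ssb / df1) / (ssw / df2)
    c(f, stats::pf(f, df1, df2, lower.tail = FALSE))
  }))
  df(feature = rownames(values) %||% as.character(seq_len(nrow(values))),
     F = res[, 1L], pvalue = res[, 2L],
     significant = !is.na(res[, 2L]) & res[, 2L] <= alpha)
}

#' Row z-scores with k-means ordering
#'
#' Standardizes each row to mean 0, sd 1 (constant rows become all-zero) and
#' partitions rows with k-means (k-means++ initialization, fixed seed,
#' Lloyd iterations) for heatmap ordering.
#'
#' @param m Numeric matrix.
#' @param k Number of clusters (1 <= k <= nrow).
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum Lloyd iterations.
#' @return List with `z` (standardized matrix) and `cluster` (row
#'   assignments).
#' @export
zscore_cluster_matrix <- function(m, k, seed = 1L, max_iter = 100L) {
  stopifnot(is.matrix(m), k >= 1L)
  if (k > nrow(m)) stopf("k exceeds number of rows")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  set.seed(seed)
  centers <- kmeanspp_init(z, k)
  cl <- if (k == 1L) rep(1L, nrow(z)) else
    stats::kmeans(z, centers = centers, iter.max = max_iter,
                  algorithm = "Lloyd")$cluster
  list(z = z, cluster = cl)
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre.
kmeanspp_init <- function(z, k) {
  n <- nrow(z)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((z - matrix(z[idx[1L], ], n, ncol(z), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1L, prob = p)
      d2j <- rowSums((z - matrix(z[idx[j], ], n, ncol(z), byrow = TRUE))^2)
      d2 <- pmin(d2, d2j)
    }
  }
  z[idx, , drop = FALSE] + matrix(stats::rnorm(k * ncol(z), 0, 1e-9),
                                  k, ncol(z))  # break exact duplicates
}
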