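test_that("tpm_normalize scales columns to one million", {
  m <- matrix(c(10, 30, 60), 3, 1, dimnames = list(paste0("f", 1:3), "s1"))
  expect_equal(as.numeric(tpm_normalize(m)), c(1e5, 3e5, 6e5))
  one <- matrix(7, 1, 1, dimnames = list("f", "s"))
  expect_equal(as.numeric(tpm_normalize(one)), 1e6)

  # transcript mode: length-normalize first
  m2 <- matrix(c(100, 100, 200, 400), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  lens <- c(1000, 2000)
  tpm <- tpm_normalize(m2, lengths = lens)
  hand <- sweep(m2 / lens, 2, colSums(m2 / lens), "/") * 1e6
  expect_equal(tpm, hand)
  expect_true(all(abs(colSums(tpm) - 1e6) < 1e-6 * 1e6))

  expect_error(tpm_normalize(matrix(0, 2, 1,
                                    dimnames = list(c("a", "b"), "s"))),
               "all-zero")
  expect_error(tpm_normalize(m2, lengths = c(0, 10)), "non-positive")
})

test_that("estimate_size_factors recovers known scalings", {
  set.seed(12)
  base <- matrix(rpois(600, 100), 200, 3)
  m <- cbind(base[, 1], base[, 1] * 2)   # sample 2 = 2 x sample 1
  sf <- estimate_size_factors(m)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
})

test_that("differential_features behaves on degenerate and planted inputs", {
  m <- matrix(rep(c(50, 80, 20, 100), each = 6), 4, 6, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  cond <- rep(c("a", "b"), each = 3)
  de <- differential_features(m, cond)
  expect_true(all(de$log2FoldChange == 0))
  expect_true(all(de$call == "unchanged"))
  expect_true(all(de$pvalue == 1))

  expect_error(differential_features(m, rep("a", 6)), "two conditions")
  expect_error(differential_features(m[, 1:3], c("a", "a", "b")),
               ">= 2 samples")

  # planted 4-fold change among nulls is called up
  set.seed(13)
  mu <- rep(500, 201)
  counts <- sapply(1:6, function(i) rnbinom(201, mu = mu, size = 10))
  counts[1, 4:6] <- rnbinom(3, mu = 2000, size = 10)
  dimnames(counts) <- list(paste0("g", 1:201), paste0("s", 1:6))
  de <- differential_features(counts, rep(c("ctl", "kd"), each = 3))
  expect_equal(de$call[1], "up")

  # call invariant: up iff padj <= 0.05 and lfc >= 1
  expect_true(all((de$call == "up") ==
                    (de$padj <= 0.05 & de$log2FoldChange >= 1)))
})

test_that("the scaled-MAD outlier rule matches its oracle", {
  x <- c(1, 1.1, 0.9, 1.05, 8)
  res <- mad_outlier_filter(x)
  expect_equal(res$values, c(1, 1.1, 0.9, 1.05))   # exactly the 8 removed
  expect_false(res$excluded)

  # hand-computed scaled MAD: median 1.05, MAD 0.05, scaled 0.07413
  expect_equal(1.4826 * stats::median(abs(x - stats::median(x))), 0.07413)

  # strict inequality at exactly 3 scaled MADs
  y <- c(-1, 0, 0, 0, 1)                    # scaled MAD 0 -> strict dev rule
  smad <- 1.4826 * stats::median(abs(y - stats::median(y)))
  expect_equal(smad, 0)
  z <- c(0, 1, 2, 3, 4)
  smadz <- 1.4826 * stats::median(abs(z - stats::median(z)))
  at_boundary <- 2 + 3 * smadz              # exactly 3 scaled MADs from median
  res2 <- mad_outlier_filter(c(z, at_boundary))
  # recompute for the 6-vector: the boundary value must NOT be removed
  zz <- c(z, at_boundary)
  s6 <- 1.4826 * stats::median(abs(zz - stats::median(zz)))
  expect_true(abs(zz[6] - stats::median(zz)) <= 3 * s6 + 1e-12)
  expect_true(res2$keep[6])

  # constant vector: nothing removed
  expect_true(all(mad_outlier_filter(rep(2, 5))$keep))

  # affine equivariance and permutation invariance
  set.seed(14)
  v <- c(rnorm(8), 9)
  k1 <- mad_outlier_filter(v)$keep
  expect_equal(mad_outlier_filter(-2.5 * v + 4)$keep, k1)
  p <- sample(9)
  expect_equal(mad_outlier_filter(v[p])$keep, k1[p])

  # the mean-centered variant is available behind a flag
  res_mean <- mad_outlier_filter(x, center = "mean")
  expect_false(any(res_mean$keep))   # mean-centering removes everything here
})

test_that("per_gene_test equals ANOVA and the squared-t identity", {
  set.seed(15)
  v <- matrix(rnorm(12, 10), 1, 12)
  cond <- rep(c("a", "b", "c"), each = 4)
  res <- per_gene_test(v, cond)
  fit <- stats::anova(stats::lm(as.numeric(v) ~ factor(cond)))
  expect_equal(res$F, fit$`F value`[1], tolerance = 1e-6)
  expect_equal(res$pvalue, fit$`Pr(>F)`[1], tolerance = 1e-6)

  # two groups: F = t^2 and p-values agree with the pooled t-test
  v2 <- matrix(rnorm(10, 5), 1, 10)
  cond2 <- rep(c("a", "b"), each = 5)
  res2 <- per_gene_test(v2, cond2)
  tt <- stats::t.test(v2[1, 1:5], v2[1, 6:10], var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(res2$pvalue, tt$p.value, tolerance = 1e-9)

  # equal group means with noise: F ~ 0, p ~ 1
  v3 <- matrix(rep(c(1, 2, 3), 4), 1, 12)
  expect_gt(per_gene_test(v3, rep(c("a", "b"), each = 6))$pvalue, 0.9)

  # degenerate: constant values give p = 1 by convention
  v4 <- matrix(5, 1, 8)
  expect_equal(per_gene_test(v4, rep(c("a", "b"), each = 4))$pvalue, 1)
})

test_that("zscore_cluster_matrix standardizes rows and recovers partitions", {
  set.seed(16)
  m <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 8), 10, 4))
  m <- m + matrix(rnorm(80, 0, 0.1), 20, 4)
  # separate the groups in pattern, not just level (z-scores drop level)
  m[1:10, 1:2] <- m[1:10, 1:2] + 5
  m[11:20, 3:4] <- m[11:20, 3:4] + 5
  res <- zscore_cluster_matrix(m, k = 2, seed = 99)
  expect_equal(unname(rowMeans(res$z)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(res$z, 1, sd)), rep(1, 20), tolerance = 1e-12)
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand(res$cluster, truth), 1)

  # constant row becomes all-zero
  m2 <- rbind(m, 0)
  res2 <- zscore_cluster_matrix(m2, k = 2, seed = 99)
  expect_true(all(res2$z[21, ] == 0))

  expect_error(zscore_cluster_matrix(m, k = 50), "exceeds")
})

test_that("differential surrogate: pure-null false-call rate is controlled", {
  set.seed(17)
  n_false <- 0L; n_feat <- 0L
  for (rep in 1:100) {
    counts <- sapply(1:6, function(i) rnbinom(200, mu = 300, size = 10))
    dimnames(counts) <- list(paste0("g", 1:200), paste0("s", 1:6))
    de <- differential_features(counts, rep(c("a", "b"), each = 3))
    n_false <- n_false + sum(de$call != "unchanged")
    n_feat <- n_feat + nrow(de)
  }
  expect_lt(n_false / n_feat, 1.5 * 0.05)
})
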