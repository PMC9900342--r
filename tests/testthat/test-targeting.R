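test_that("categorize_pirnas applies the precedence rule", {
  repeats <- data.frame(chrom = "chr1", start = c(100L, 500L),
                        end = c(200L, 600L),
                        family = c("SINEB1", "LINE1"),
                        stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "chr1", start = 50L, end = 250L,
                      stringsAsFactors = FALSE)
  clusters <- data.frame(chrom = "chr1", start = 800L, end = 900L,
                         stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "chr1",
                     start = c(150L, 520L, 60L, 820L, 1000L),
                     end   = c(180L, 550L, 90L, 850L, 1030L),
                     name = paste0("p", 1:5), stringsAsFactors = FALSE)
  res <- categorize_pirnas(loci, repeats, genes, clusters)
  expect_equal(res$categories$category,
               c("RE_within_GENCODE",   # repeat inside gene
                 "RE_only",             # repeat only
                 "GENCODE_element",     # gene only
                 "cluster_member",      # called cluster only
                 "unannotated"))
  expect_equal(res$categories$family[1:2], c("SINEB1", "LINE1"))

  bad <- loci; bad$chrom <- "chrX"
  expect_error(categorize_pirnas(bad, repeats, genes), "mismatch")
})

test_that("categorize_pirnas recovers a planted family mixture", {
  set.seed(18)
  n <- 5000L
  fam <- sample(c("5S_rRNA", "tRNA", "other_RE"), n, replace = TRUE,
                prob = c(0.47, 0.40, 0.13))
  # one repeat interval per locus, locus inside it
  starts <- seq(0L, by = 500L, length.out = n)
  repeats <- data.frame(chrom = "chr1", start = starts, end = starts + 400L,
                        family = fam, stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "chr1", start = starts + 100L,
                     end = starts + 130L, stringsAsFactors = FALSE)
  no_genes <- data.frame(chrom = "chr1", start = 0L, end = 1L,
                         stringsAsFactors = FALSE)[0, ]
  res <- categorize_pirnas(loci, repeats, no_genes)
  p <- res$family_proportions
  expect_equal(unname(p["5S_rRNA"]), 0.47, tolerance = 0.05)
  expect_equal(unname(p["tRNA"]), 0.40, tolerance = 0.05)
  expect_true(all(res$categories$category == "RE_only"))
})

test_that("predict_targets finds sense and antisense sites", {
  set.seed(19)
  pirnas <- data.frame(id = paste0("pi", 1:3), sequence = random_dna(3, 28),
                       tpm = c(10, 20, 30), stringsAsFactors = FALSE)
  bg <- random_dna(3, 300)
  tx <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g2", "g3"),
    sequence = c(paste0(substr(bg[1], 1, 100), oracle_revcomp(pirnas$sequence[1]),
                        substr(bg[1], 101, 200)),       # antisense site
                 paste0(substr(bg[2], 1, 100), pirnas$sequence[2],
                        substr(bg[2], 101, 200)),       # sense (homology) site
                 bg[3]),                                 # no site
    stringsAsFactors = FALSE)
  res <- predict_targets(pirnas, tx)
  rep1 <- res$reports[res$reports$gene_id == "g1", ]
  rep2 <- res$reports[res$reports$gene_id == "g2", ]
  rep3 <- res$reports[res$reports$gene_id == "g3", ]
  expect_true(rep1$is_target)
  expect_equal(rep1$antisense_sites, 1L)
  expect_true(rep2$is_target)
  expect_equal(rep2$sense_sites, 1L)
  expect_false(rep3$is_target)
  expect_equal(rep3$n_unique_targeting_pirnas, 0L)

  # a 2-mismatch best site under defaults is not a target (oracle-checked)
  two <- pirnas$sequence[3]
  substr(two, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(two, 5, 5))[1]
  substr(two, 24, 24) <- setdiff(c("A", "C", "G", "T"), substr(two, 24, 24))[1]
  tx2 <- data.frame(transcript_id = "t4", gene_id = "g4",
                    sequence = paste0(substr(bg[3], 1, 50), two,
                                      substr(bg[3], 51, 120)),
                    stringsAsFactors = FALSE)
  expect_false(oracle_hit_exists(pirnas$sequence[3], tx2$sequence))
  res2 <- predict_targets(pirnas[3, ], tx2)
  expect_false(res2$reports$is_target)

  expect_error(predict_targets(pirnas, tx[0, ]), "empty transcriptome")
})

test_that("unique-piRNA counting is idempotent under duplicated sites", {
  set.seed(20)
  p <- random_dna(1, 28)
  pirnas <- data.frame(id = "piA", sequence = p, tpm = 12,
                       stringsAsFactors = FALSE)
  spacer <- random_dna(1, 60)
  # same piRNA planted in two transcripts of one gene, twice in one of them
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                   sequence = c(paste0(spacer, p, spacer, p, spacer),
                                paste0(spacer, oracle_revcomp(p), spacer)),
                   stringsAsFactors = FALSE)
  res <- predict_targets(pirnas, tx)
  expect_equal(res$reports$n_unique_targeting_pirnas, 1L)
  expect_equal(res$reports$summed_targeting_tpm, 12)
})

test_that("target_load_summary aggregates per-gene loads", {
  reports <- data.frame(gene_id = c("g1", "g2"),
                        n_unique_targeting_pirnas = c(3L, 0L),
                        summed_targeting_tpm = c(60, 0),
                        sense_sites = c(1L, 0L), antisense_sites = c(2L, 0L),
                        is_target = c(TRUE, FALSE),
                        modulated = c(TRUE, TRUE),
                        stringsAsFactors = FALSE)
  s <- target_load_summary(reports)
  expect_equal(s$max_unique_pirnas, 3L)
  expect_equal(s$max_summed_tpm, 60)
  expect_equal(s$modulated_targets, 1L)
  expect_equal(s$modulated_nontargets, 1L)
})

test_that("ks_compare matches enumeration exactly for small samples", {
  expect_equal(ks_compare(1:5, 1:5)$statistic, 0)
  expect_equal(ks_compare(1:5, 1:5)$p.value, 1)
  ks <- ks_compare(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(ks$statistic, 1)

  set.seed(21)
  x <- rnorm(4); y <- rnorm(4, 1)
  got <- ks_compare(x, y)
  expect_equal(got$method, "exact enumeration")
  expect_equal(got$p.value, oracle_ks_exact(x, y))
  # ties handled by enumeration as well
  xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4)
  expect_equal(ks_compare(xt, yt)$p.value, oracle_ks_exact(xt, yt))

  # asymptotic branch agrees with the classical approximation
  set.seed(22)
  a <- rnorm(60); b <- rnorm(80, 0.8)
  got2 <- ks_compare(a, b)
  expect_equal(got2$method, "asymptotic")
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(got2$statistic, unname(ref$statistic))
  expect_equal(got2$p.value, ref$p.value, tolerance = 0.02)
  expect_true(got2$statistic >= 0 && got2$statistic <= 1)

  expect_error(ks_compare(numeric(0), 1:3), "empty")
})

test_that("spearman_targets follows the rank-then-Pearson definition", {
  expect_equal(spearman_targets(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_targets(1:10, -(1:10)^3)$rho, -1)
  expect_equal(spearman_targets(1:10, (1:10)^3)$p.value, 0)

  # tied example, expected rho computed by hand:
  # ranks x = (1, 2.5, 2.5, 4); ranks y = (3, 1.5, 1.5, 4); rho = 1/3
  x <- c(1, 2, 2, 4); y <- c(7, 5, 5, 9)
  expect_equal(spearman_targets(x, y)$rho, 1 / 3)

  expect_error(spearman_targets(rep(1, 5), 1:5), "constant")
  expect_error(spearman_targets(1:2, 1:2), "at least 3")
})
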