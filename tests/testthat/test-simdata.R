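test_that("sim_config validates its stated world", {
  cfg <- sim_config()
  expect_equal(sum(cfg$length_distribution), 1)
  expect_equal(as.integer(names(which.max(cfg$length_distribution))), 30L)
  expect_equal(cfg$u_bias, 0.8)
  expect_error(sim_config(u_bias = 1.5), "fraction")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(length_distribution = c("30" = 0.5)), "sum to 1")
  expect_error(sim_config(genome_size = 1000), "infeasible")
})

test_that("sim_genome is deterministic and plants what it claims", {
  cfg <- small_sim(n_clusters = 5L)
  g1 <- sim_genome(cfg)
  g2 <- sim_genome(cfg)
  expect_identical(g1, g2)                       # byte-identical under a seed

  expect_equal(nrow(g1$clusters), 5L)
  # truth clusters pairwise disjoint
  for (ch in unique(g1$clusters$chrom)) {
    sub <- g1$clusters[g1$clusters$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L)
      expect_true(all(sub$start[-1L] >= sub$end[-nrow(sub)]))
  }

  # every reference piRNA occurs verbatim at its truth locus
  ann <- g1$annotations
  at_locus <- unname(substring(g1$genome[ann$chrom], ann$start + 1L, ann$end))
  expect_identical(at_locus, g1$pirna_ref$sequence[match(ann$name,
                                                         g1$pirna_ref$id)])
  # and is findable as a substring of the genome (search oracle)
  idx <- sample(nrow(g1$pirna_ref), 25)
  expect_true(all(vapply(g1$pirna_ref$sequence[idx], function(s)
    any(grepl(s, g1$genome, fixed = TRUE)), TRUE)))

  # adjacent annotations overlap within a cluster (single merged cluster)
  for (cl in unique(ann$cluster)) {
    sub <- ann[ann$cluster == cl, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L)
      expect_true(all(sub$start[-1L] < sub$end[-nrow(sub)]))
  }
})

test_that("sim_reads honours the per-read structure and truth bookkeeping", {
  w <- small_world()
  rd <- w$reads
  expect_equal(nrow(rd$truth), nrow(rd$reads))   # one origin row per read
  expect_identical(rd$truth$id, rd$reads$id)

  # contaminants are exact substrings of their ncRNA reference class
  contam <- rd$truth[rd$truth$origin == "ncrna", ][1:20, ]
  ins <- substr(rd$reads$sequence[match(contam$id, rd$reads$id)], 1,
                contam$insert_length)
  for (i in seq_len(nrow(contam))) {
    refs <- w$ncrna$sequence[w$ncrna$class == contam$ncrna_class[i]]
    expect_true(any(grepl(ins[i], refs, fixed = TRUE)))
  }

  # piRNA inserts are exact genome substrings at the recorded site
  pi_t <- rd$truth[rd$truth$origin != "ncrna", ]
  some <- pi_t[sample(nrow(pi_t), 50), ]
  ins <- unname(substring(w$genome$genome[some$chrom], some$site_pos + 1L,
                          some$site_pos + some$insert_length))
  expect_identical(ins, substr(rd$reads$sequence[match(some$id, rd$reads$id)],
                               1, some$insert_length))

  # u_bias = 1 makes every primary read start with T
  w1 <- small_world(u_bias = 1)
  tr <- w1$reads$truth
  expect_true(all(tr$is_1u[tr$origin == "primary"]))

  # determinism
  w2 <- small_world()
  expect_identical(w2$reads$reads, rd$reads)
})

test_that("secondary 5' ends sit at kernel offsets from a primary 5' end", {
  # near-point-mass kernel at +1
  w <- small_world(distance_kernel = c("1" = 1))
  st <- w$genome$sites
  sec <- st[st$type == "secondary", ]
  expect_true(all(sec$delta == 1L))
  expect_true(all(sec$pos == sec$partner_pos + 1L))
  # partners are planted primary sites
  prim_pos <- st$pos[st$type == "primary"]
  expect_true(all(sec$partner_pos %in% prim_pos))
})

test_that("per-cluster read counts match the multinomial expectation", {
  w <- small_world(reads_per_sample = 20000L)
  tr <- w$reads$truth
  p <- w$reads$expected_cluster_prob
  for (s in colnames(p)) {
    sub <- tr[tr$sample == s & tr$origin != "ncrna", ]
    n <- nrow(sub)
    obs <- table(factor(sub$cluster, levels = rownames(p)))
    expected <- n * p[, s]
    z <- (as.numeric(obs) - expected) / sqrt(expected * (1 - p[, s]))
    expect_true(all(abs(z) < 4.5))  # 8 cluster x sample checks per sample
  }
})

test_that("sim_expression plants the stated knockdown effect", {
  cfg <- sim_config(seed = 5, n_genes = 2000L)
  ex <- sim_expression(cfg)
  expect_identical(dim(ex$counts), c(2000L, 12L))
  expect_equal(sum(ex$truth$is_target), 400L)

  # kd_effect == +1: empirical mean log2FC of targeted genes ~ 1 +/- 0.1
  fc <- log2((rowMeans(ex$counts[, 7:12]) + 0.5) /
               (rowMeans(ex$counts[, 1:6]) + 0.5))
  expect_equal(mean(fc[ex$truth$is_target]), 1, tolerance = 0.1)
  expect_equal(mean(fc[!ex$truth$is_target]), 0, tolerance = 0.05)

  # null case: target and nontarget fold changes indistinguishable
  ex0 <- sim_expression(sim_config(seed = 6, kd_log2fc = 0))
  fc0 <- log2((rowMeans(ex0$counts[, 7:12]) + 0.5) /
                (rowMeans(ex0$counts[, 1:6]) + 0.5))
  ks <- ks_compare(fc0[ex0$truth$is_target], fc0[!ex0$truth$is_target])
  expect_gt(ks$p.value, 0.01)

  # determinism
  expect_identical(sim_expression(cfg)$counts, ex$counts)
})

test_that("sim_transcriptome plants retrievable sites", {
  cfg <- small_sim()
  g <- sim_genome(cfg)
  tx <- sim_transcriptome(g$pirna_ref[1:50, ], n_genes = 30L, seed = 3)
  expect_equal(nrow(tx$transcripts), 30L)
  expect_gt(nrow(tx$truth), 0L)
  for (i in seq_len(min(10, nrow(tx$truth)))) {
    row <- tx$truth[i, ]
    tseq <- tx$transcripts$sequence[tx$transcripts$gene_id == row$gene_id]
    pseq <- g$pirna_ref$sequence[g$pirna_ref$id == row$pirna]
    want <- if (row$orientation == "antisense") oracle_revcomp(pseq) else pseq
    expect_identical(substr(tseq, row$position,
                            row$position + nchar(want) - 1L), want)
  }
})

test_that("sim_write emits a loadable dataset", {
  dir <- withr::local_tempdir()
  sim_write(small_sim(reads_per_sample = 500L), dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  inputs <- pipeline_inputs(dir)
  expect_equal(length(inputs$genome), 2L)
  expect_equal(sort(unique(inputs$reads$sample)), c("DIF0_1", "DIF4_1"))
  expect_equal(nrow(inputs$truth_clusters), 4L)
})
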