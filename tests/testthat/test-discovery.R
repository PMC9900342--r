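test_that("match_pirbase implements the zero-mismatch contract", {
  set.seed(4)
  refs <- data.frame(id = paste0("p", 1:3), sequence = random_dna(3, 28),
                     stringsAsFactors = FALSE)
  identical_read <- refs$sequence[1]
  sub_read <- substr(refs$sequence[2], 2, 27)          # contained in ref
  super_read <- paste0("ACG", refs$sequence[3], "TT")  # contains ref
  one_off <- refs$sequence[1]
  substr(one_off, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(one_off, 10, 10))[1]
  res <- match_pirbase(c(identical_read, sub_read, super_read, one_off), refs)
  expect_setequal(res$matched$sequence, c(identical_read, sub_read, super_read))

  # matching is sense-only by default
  rc <- oracle_revcomp(refs$sequence[1])
  expect_equal(nrow(match_pirbase(rc, refs)$matched), 0L)
  expect_equal(nrow(match_pirbase(rc, refs,
                                  orientations = c("sense", "antisense"))$matched),
               1L)
})

test_that("align_genome reports all exact placements deterministically", {
  set.seed(5)
  chr1 <- random_dna(1, 3000)
  read <- substr(chr1, 500, 529)
  genome <- c(chr1 = chr1,
              chr2 = paste0(random_dna(1, 400), read, random_dna(1, 300),
                            read, random_dna(1, 200)))
  al <- align_genome(read, genome)
  # unique occurrence on chr1 plus two planted on chr2 (up to chance extras)
  expect_true(nrow(al) >= 3L)
  expect_true(any(al$chrom == "chr1" & al$start == 499L & al$end == 529L &
                    al$strand == "+"))
  expect_equal(sum(al$chrom == "chr2" & al$strand == "+"), 2L)
  # deterministic (chrom, start) order
  expect_identical(al, al[order(al$chrom, al$start, al$sequence), ])

  # minus-strand placement
  rc <- oracle_revcomp(read)
  al2 <- align_genome(rc, genome)
  expect_true(all(al2$strand == "-"))
  expect_equal(nrow(al2), nrow(al))
  expect_equal(al2$start, al$start)

  # a read with no occurrence is dropped and counted
  novel <- random_dna(1, 30)
  al3 <- align_genome(c(read, novel), genome)
  expect_equal(attr(al3, "n_unaligned"), 1L)
})

test_that("align_genome caps placements at the configured maximum", {
  motif <- "ACGTGCATTGACGTAGCATGACGTACGTA"   # 29 nt
  genome <- c(chrR = paste(c(rbind(random_dna(150, 40),
                                   rep(motif, 150))), collapse = ""))
  al <- align_genome(motif, genome, cap = 100L)
  expect_equal(nrow(al), 100L)
  al_full <- align_genome(motif, genome, cap = 1000L)
  expect_equal(nrow(al_full), 150L)
  expect_equal(attr(al, "n_capped"), 1L)
  # the first cap placements in coordinate order are kept
  expect_equal(al$start, sort(al_full$start)[1:100])
})

test_that("call_clusters merges overlapping and book-ended intervals", {
  ann <- data.frame(chrom = "chr1",
                    start = c(100L, 120L, 150L),
                    end = c(130L, 150L, 180L),
                    name = c("a", "b", "c"), stringsAsFactors = FALSE)
  cl <- call_clusters(ann)
  expect_equal(nrow(cl), 1L)      # [120,150) overlaps, [150,180) book-ends
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 180L)
  expect_equal(cl$members, "a,b,c")

  # a 1-base gap keeps clusters separate
  ann2 <- data.frame(chrom = "chr1", start = c(100L, 131L),
                     end = c(130L, 160L), stringsAsFactors = FALSE)
  expect_equal(nrow(call_clusters(ann2)), 2L)

  # single 30-nt annotation: cluster length 30
  one <- call_clusters(data.frame(chrom = "chr2", start = 10L, end = 40L,
                                  stringsAsFactors = FALSE))
  expect_equal(one$length, 30L)
})

test_that("count_cluster_reads implements -f 1 and multiplicity linearity", {
  clusters <- data.frame(id = c("c1", "c2"), chrom = "chr1",
                         start = c(100L, 300L), end = c(200L, 400L),
                         stringsAsFactors = FALSE)
  alignments <- data.frame(sequence = c("s1", "s2", "s3", "s3"),
                           chrom = "chr1",
                           start = c(100L, 180L, 310L, 390L),
                           end   = c(200L, 210L, 340L, 420L),
                           strand = "+", stringsAsFactors = FALSE)
  reads <- data.frame(sequence = c("s1", "s2", "s3"),
                      count = c(2L, 3L, 5L), sample = "a",
                      stringsAsFactors = FALSE)
  counts <- count_cluster_reads(alignments, clusters, reads)
  expect_equal(counts["c1", "a"], 2)   # s1 equals the interval: counted
  # s2 straddles the c1 boundary, s3's second placement straddles c2
  expect_equal(counts["c2", "a"], 5)

  # doubling every multiplicity doubles every count
  reads2 <- reads; reads2$count <- reads2$count * 2L
  expect_equal(count_cluster_reads(alignments, clusters, reads2), counts * 2)

  # fractional weighting divides by the number of placements
  frac <- count_cluster_reads(alignments, clusters, reads,
                              weighting = "fractional")
  expect_equal(frac["c2", "a"], 2.5)

  # overlapping clusters violate the precondition
  bad <- clusters; bad$start[2] <- 150L; bad$end[2] <- 250L
  expect_error(count_cluster_reads(alignments, bad, reads), "overlap")
})

test_that("cluster_summary aggregates lengths and counts", {
  cl <- data.frame(id = c("c1", "c2"), chrom = c("chr1", "chr2"),
                   start = c(0L, 0L), end = c(100L, 200L),
                   length = c(100L, 200L), stringsAsFactors = FALSE)
  counts <- matrix(c(10, 30), 2, 1, dimnames = list(cl$id, "s"))
  s <- cluster_summary(cl, counts)
  expect_equal(s$n_clusters, 2L)
  expect_equal(s$mean_length, 150)
  expect_equal(s$max_reads_per_cluster, 30)
  expect_equal(as.numeric(s$per_chromosome[c("chr1", "chr2")]), c(1, 1))
  expect_error(cluster_summary(cl[0, ]), "no clusters")
})

test_that("read_sam imports ungapped records with strand handling", {
  f <- withr::local_tempfile(fileext = ".sam")
  seq <- "ACGTACGTACGTACGTACGTACGTACGTA"
  writeLines(c("@HD\tVN:1.6",
               paste("r1", 0, "chr1", 101, 42, "29M", "*", 0, 0, seq, "*",
                     sep = "\t"),
               paste("r2", 16, "chr1", 201, 42, "29M", "*", 0, 0, seq, "*",
                     sep = "\t"),
               paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, seq, "*",
                     sep = "\t")), f)
  x <- read_sam(f)
  expect_equal(nrow(x), 2L)
  expect_equal(x$start, c(100L, 200L))
  expect_equal(x$strand, c("+", "-"))
  # minus-strand sequence is reported in genome-forward orientation in SAM,
  # so the original read is its reverse complement
  expect_equal(x$sequence[2], oracle_revcomp(seq))
})
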