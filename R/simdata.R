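#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generator. Defaults encode
#' the data structure the analysis assumes: 24-35 nt reads with modal length
#' 30, a 0.8 fraction of reads with 5' uridine, piRNA clusters with skewed
#' abundances peaking at the DIF4-like timepoint (two replicates each of
#' DIF0/DIF4/DIF7), secondary reads whose 5' termini sit within +/-2 nt of a
#' primary 5' end, 5% contaminant ncRNA reads, a 3' sequencing adapter, and a
#' knockdown-vs-control expression table in which targeted genes are
#' upregulated by one log2 unit.
#'
#' @param seed Integer master seed; all generator randomness derives from it.
#' @param genome_size Total genome size in bases (split across `n_chrom`).
#' @param n_chrom Number of chromosomes.
#' @param n_clusters Number of planted piRNA clusters.
#' @param cluster_length_range Hard bounds on cluster lengths (bases), used
#'   for the packing feasibility check.
#' @param cluster_length_meanlog,cluster_length_sdlog Log-normal body of the
#'   cluster length distribution; defaults give a mean near 170 bases,
#'   matching reported cluster sizes.
#' @param cluster_length_long_fraction,cluster_length_long_range A small
#'   fraction of clusters is drawn uniformly from this long range (the
#'   "some clusters exceed 2 kb" tail).
#' @param pirna_length_range Annotated piRNA lengths (bases).
#' @param tile_step_range Distance between adjacent annotated piRNA starts.
#'   The maximum is below the minimum piRNA length, so adjacent annotations
#'   always overlap and each planted cluster merges into one called cluster;
#'   the dense default (2-6 nt) reflects the observed density of distinct
#'   piRNA sequences per cluster (thousands per ~170-base cluster).
#' @param reads_per_sample Reads simulated per sample.
#' @param length_distribution Named probability vector over read lengths
#'   24-35 with mode 30.
#' @param u_bias Per-read probability that a primary read starts with T.
#' @param t_site_fraction Fraction of primary sites planted with a T start
#'   (both site types exist in every cluster so `u_bias` can be honoured
#'   read-by-read).
#' @param secondary_fraction Fraction of piRNA reads drawn from secondary
#'   (10A-signature) sites.
#' @param secondary_site_ratio Secondary sites per primary site.
#' @param distance_kernel Named probability vector of signed 5'-5' offsets
#'   for secondary sites. Offset 0 is excluded by default: a site cannot
#'   carry both the primary (1U) and secondary (non-T + 10A) signature.
#' @param contaminant_fraction Fraction of reads drawn from ncRNA references.
#' @param adapter 3' adapter sequence appended to every read.
#' @param read_length Instrument read length; inserts are padded/truncated.
#' @param quality_char Constant base quality (phred+33 character).
#' @param quality_decay Mean number of low-quality (phred 2) 3' tail bases
#'   per read; 0 disables the quality-trimming exercise.
#' @param samples data.frame with columns `sample` and `condition`; default
#'   two replicates each of DIF0/DIF4/DIF7.
#' @param dynamic_fraction Fraction of clusters with condition-dependent
#'   abundance.
#' @param dynamic_multipliers Named per-condition abundance multipliers for
#'   dynamic clusters (peaking at DIF4, as observed for piRNA expression).
#' @param n_genes,targeted_fraction Knockdown table dimensions.
#' @param kd_log2fc,kd_sd Mean and sd of the log2 fold change planted on
#'   piRNA-targeted genes in the knockdown condition.
#' @param expr_meanlog,expr_sdlog Log-normal distribution of baseline gene
#'   means.
#' @param dispersion Negative-binomial dispersion of the expression counts.
#' @param n_reps_expr Replicates per condition in the expression table
#'   (six sequencing runs per genotype, as in the modelled experiment).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_size = 100000L,
                       n_chrom = 3L,
                       n_clusters = 10L,
                       cluster_length_range = c(80L, 2500L),
                       cluster_length_meanlog = log(120),
                       cluster_length_sdlog = 0.45,
                       cluster_length_long_fraction = 0.03,
                       cluster_length_long_range = c(1500L, 2500L),
                       pirna_length_range = c(25L, 32L),
                       tile_step_range = c(2L, 6L),
                       reads_per_sample = 200000L,
                       length_distribution = c(
                         "24" = 0.02, "25" = 0.03, "26" = 0.05, "27" = 0.08,
                         "28" = 0.12, "29" = 0.15, "30" = 0.22, "31" = 0.13,
                         "32" = 0.09, "33" = 0.06, "34" = 0.03, "35" = 0.02),
                       u_bias = 0.8,
                       t_site_fraction = 0.5,
                       secondary_fraction = 0.3,
                       secondary_site_ratio = 0.5,
                       distance_kernel = c("-2" = 0.15, "-1" = 0.35,
                                           "1" = 0.35, "2" = 0.15),
                       contaminant_fraction = 0.05,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50L,
                       quality_char = "I",
                       quality_decay = 0,
                       samples = NULL,
                       dynamic_fraction = 0.5,
                       dynamic_multipliers = c(DIF0 = 1, DIF4 = 4, DIF7 = 2),
                       n_genes = 2000L,
                       targeted_fraction = 0.2,
                       kd_log2fc = 1,
                       kd_sd = 0,
                       expr_meanlog = log(200),
                       expr_sdlog = 1,
                       dispersion = 0.1,
                       n_reps_expr = 6L) {
  if (is.null(samples)) {
    conds <- names(dynamic_multipliers)
    samples <- df(sample = paste0(rep(conds, each = 2L), "_", 1:2),
                  condition = rep(conds, each = 2L))
  }
  assert_cols(samples, c("sample", "condition"))
  cfg <- list(seed = as.integer(seed), genome_size = as.integer(genome_size),
              n_chrom = as.integer(n_chrom), n_clusters = as.integer(n_clusters),
              cluster_length_range = as.integer(cluster_length_range),
              cluster_length_meanlog = cluster_length_meanlog,
              cluster_length_sdlog = cluster_length_sdlog,
              cluster_length_long_fraction = cluster_length_long_fraction,
              cluster_length_long_range = as.integer(cluster_length_long_range),
              pirna_length_range = as.integer(pirna_length_range),
              tile_step_range = as.integer(tile_step_range),
              reads_per_sample = as.integer(reads_per_sample),
              length_distribution = length_distribution,
              u_bias = u_bias, t_site_fraction = t_site_fraction,
              secondary_fraction = secondary_fraction,
              secondary_site_ratio = secondary_site_ratio,
              distance_kernel = distance_kernel,
              contaminant_fraction = contaminant_fraction,
              adapter = toupper(adapter), read_length = as.integer(read_length),
              quality_char = quality_char, quality_decay = quality_decay,
              samples = samples, dynamic_fraction = dynamic_fraction,
              dynamic_multipliers = dynamic_multipliers,
              n_genes = as.integer(n_genes),
              targeted_fraction = targeted_fraction,
              kd_log2fc = kd_log2fc, kd_sd = kd_sd,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              dispersion = dispersion, n_reps_expr = as.integer(n_reps_expr))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs_one <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stopf("%s must be non-negative and sum to 1", what)
  }
  probs_one(cfg$length_distribution, "length_distribution")
  probs_one(cfg$distance_kernel, "distance_kernel")
  fr <- c(u_bias = cfg$u_bias, t_site_fraction = cfg$t_site_fraction,
          secondary_fraction = cfg$secondary_fraction,
          contaminant_fraction = cfg$contaminant_fraction,
          targeted_fraction = cfg$targeted_fraction,
          dynamic_fraction = cfg$dynamic_fraction)
  if (any(fr < 0 | fr > 1))
    stopf("fraction out of [0,1]: %s", paste(names(fr)[fr < 0 | fr > 1],
                                             collapse = ", "))
  if (cfg$dispersion <= 0) stopf("non-positive dispersion")
  if (cfg$genome_size < cfg$n_clusters * max(cfg$cluster_length_range) * 3L)
    stopf("infeasible packing: genome_size must be >= n_clusters x max cluster length x 3")
  if (!all(cfg$samples$condition %in% names(cfg$dynamic_multipliers)))
    stopf("sample condition without a dynamic multiplier")
  invisible(cfg)
}

BASES <- c("A", "C", "G", "T")

#' Simulate a genome with planted piRNA clusters
#'
#' Generates a random genome, places non-overlapping clusters, tiles each
#' cluster with overlapping annotated piRNA sites (so merging recovers
#' exactly one cluster per planted locus), plants the 1U/10A sequence
#' signatures, and derives the reference piRNA set from the primary sites.
#'
#' Primary sites are forced to start with T (`t_site_fraction` of them) or a
#' non-T base; secondary sites, offset from a primary partner by a draw from
#' `distance_kernel`, are forced to a non-T start and an A at position 10.
#' Because signature forcing can collide (e.g. a secondary's position-10 A
#' landing on a primary start), site signatures are re-read from the final
#' genome: the truth table always reflects realized sequence.
#'
#' @param config A [sim_config()] object.
#' @return List of class `sim_genome` with elements `genome` (named character
#'   vector of chromosome sequences), `pirna_ref` (reference piRNA
#'   data.frame), `annotations` (primary piRNA loci, 0-based half-open),
#'   `clusters` (truth intervals), `sites` (all primary/secondary sites),
#'   `cluster_weights`, `multipliers` (condition x cluster abundance matrix)
#'   and `config`.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- paste0("chr", seq_len(config$n_chrom))
  sizes <- rep(config$genome_size %/% config$n_chrom, config$n_chrom)
  sizes[1L] <- sizes[1L] + config$genome_size %% config$n_chrom
  names(sizes) <- chrom_names
  chars <- lapply(sizes, function(n) sample(BASES, n, replace = TRUE))

  # log-normal body (mean ~170 bases) with a rare long tail beyond 1.5 kb
  lens <- round(stats::rlnorm(config$n_clusters,
                              config$cluster_length_meanlog,
                              config$cluster_length_sdlog))
  lens <- pmin(pmax(lens, config$cluster_length_range[1L]),
               config$cluster_length_range[2L])
  long <- stats::runif(config$n_clusters) < config$cluster_length_long_fraction
  if (any(long))
    lens[long] <- round(stats::runif(sum(long),
                                     config$cluster_length_long_range[1L],
                                     config$cluster_length_long_range[2L]))
  chrom_of <- sort(sample(config$n_chrom, config$n_clusters, replace = TRUE,
                          prob = sizes / sum(sizes)))
  margin <- 300L  # clearance between clusters and from chromosome ends
  placements <- vector("list", config$n_clusters)
  idx <- 0L
  for (ci in seq_len(config$n_chrom)) {
    ks <- which(chrom_of == ci)
    if (!length(ks)) next
    need <- sum(lens[ks]) + (length(ks) + 1L) * margin
    free <- sizes[ci] - need
    if (free < 0) stopf("infeasible packing on %s", chrom_names[ci])
    extra <- diff(c(0, sort(stats::runif(length(ks))), 1)) * free
    pos <- margin + floor(extra[1L])
    for (j in seq_along(ks)) {
      idx <- idx + 1L
      placements[[idx]] <- list(cluster = ks[j], chrom = chrom_names[ci],
                                start = as.integer(pos),
                                len = lens[ks[j]])
      pos <- pos + lens[ks[j]] + margin + floor(extra[j + 1L])
    }
  }

  sites <- list()
  for (pl in placements) {
    k <- pl$cluster
    s <- pl$start; e <- pl$start + pl$len
    pos <- s
    prim <- list()
    while (TRUE) {
      plen <- sample(seq(config$pirna_length_range[1L],
                         config$pirna_length_range[2L]), 1L)
      if (pos + plen > e) break
      prim[[length(prim) + 1L]] <- c(pos = pos, len = plen)
      pos <- pos + sample(seq(config$tile_step_range[1L],
                              config$tile_step_range[2L]), 1L)
    }
    if (length(prim) < 2L)
      stopf("cluster %d too short to tile at least two piRNA sites", k)
    pp <- do.call(rbind, prim)
    n_p <- nrow(pp)
    n_t <- max(1L, min(n_p - 1L, round(config$t_site_fraction * n_p)))
    t_idx <- sample(n_p, n_t)
    # secondary sites: offset from a T-start partner by a kernel draw
    n_s <- max(1L, round(config$secondary_site_ratio * n_p))
    offs <- as.integer(names(config$distance_kernel))
    # secondary sites may coincide with non-T primary starts (annotated
    # piRNA collections contain secondary piRNAs too); the secondary
    # signature forcing, applied last, wins at such positions. Two
    # collisions are forbidden because they would erase a planted T start
    # (the 1U signal) and skew the 5'-5' distance geometry: a secondary
    # start on a T site, and a secondary position-10 A landing on one.
    t_pos <- unname(pp[t_idx, "pos"])
    sec <- list()
    taken <- integer(0)
    for (j in seq_len(n_s)) {
      for (try in 1:20) {
        partner <- t_idx[sample.int(length(t_idx), 1L)]
        delta <- sample(offs, 1L, prob = config$distance_kernel)
        ppos <- unname(pp[partner, "pos"])
        spos <- ppos + delta
        if (spos >= s && !(spos %in% taken) && !(spos %in% t_pos) &&
            !((spos + 9L) %in% t_pos)) {
          sec[[length(sec) + 1L]] <- c(pos = spos, partner_pos = ppos,
                                       delta = delta)
          taken <- c(taken, spos)
          break
        }
      }
    }
    cl_id <- sprintf("cluster_%02d", k)
    sites[[length(sites) + 1L]] <-
      df(cluster = cl_id, chrom = pl$chrom, pos = as.integer(pp[, "pos"]),
         len = as.integer(pp[, "len"]), type = "primary",
         t_planted = seq_len(n_p) %in% t_idx,
         partner_pos = NA_integer_, delta = NA_integer_)
    if (length(sec)) {
      sm <- do.call(rbind, sec)
      sites[[length(sites) + 1L]] <-
        df(cluster = cl_id, chrom = pl$chrom, pos = as.integer(sm[, "pos"]),
           len = NA_integer_, type = "secondary", t_planted = FALSE,
           partner_pos = as.integer(sm[, "partner_pos"]),
           delta = as.integer(sm[, "delta"]))
    }
  }
  sites <- do.call(rbind, sites)

  # plant sequence signatures, primaries first, then secondaries
  non_t <- c("A", "C", "G")
  for (i in which(sites$type == "primary")) {
    chars[[sites$chrom[i]]][sites$pos[i] + 1L] <-
      if (sites$t_planted[i]) "T" else sample(non_t, 1L)
  }
  for (i in which(sites$type == "secondary")) {
    chars[[sites$chrom[i]]][sites$pos[i] + 1L] <- sample(non_t, 1L)
    chars[[sites$chrom[i]]][sites$pos[i] + 10L] <- "A"
  }
  # re-read realized signatures from the final genome
  first_base <- mapply(function(ch, p) chars[[ch]][p + 1L],
                       sites$chrom, sites$pos)
  tenth_base <- mapply(function(ch, p) chars[[ch]][p + 10L],
                       sites$chrom, sites$pos)
  sites$t_start <- first_base == "T"
  sites$signature_ok <- ifelse(sites$type == "primary",
                               sites$t_start == sites$t_planted,
                               !sites$t_start & tenth_base == "A")

  genome <- vapply(chars, paste, "", collapse = "")

  prim <- sites[sites$type == "primary", , drop = FALSE]
  prim_id <- sprintf("pi_%s_%03d", prim$cluster,
                     as.integer(stats::ave(seq_len(nrow(prim)), prim$cluster,
                                           FUN = seq_along)))
  annotations <- df(chrom = prim$chrom, start = prim$pos,
                    end = prim$pos + prim$len, name = prim_id, score = 0,
                    strand = "+", cluster = prim$cluster)
  pirna_ref <- df(id = prim_id,
                  sequence = substring(genome[prim$chrom], prim$pos + 1L,
                                       prim$pos + prim$len))

  spl <- split(seq_len(nrow(annotations)), annotations$cluster)
  clusters <- do.call(rbind, lapply(names(spl), function(cl) {
    i <- spl[[cl]]
    df(chrom = annotations$chrom[i][1L],
       start = min(annotations$start[i]),
       end = max(annotations$end[i]),
       name = cl, score = 0, strand = "+")
  }))
  clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
  rownames(clusters) <- NULL

  w <- stats::rgamma(config$n_clusters, shape = 1)
  w <- w / sum(w)
  dyn <- stats::runif(config$n_clusters) < config$dynamic_fraction
  mult <- sapply(seq_len(config$n_clusters), function(k) {
    if (dyn[k]) config$dynamic_multipliers else
      rep(1, length(config$dynamic_multipliers))
  })
  rownames(mult) <- names(config$dynamic_multipliers)
  colnames(mult) <- sprintf("cluster_%02d", seq_len(config$n_clusters))

  structure(list(genome = genome, pirna_ref = pirna_ref,
                 annotations = annotations, clusters = clusters,
                 sites = sites, cluster_weights = w, dynamic = dyn,
                 multipliers = mult, config = config),
            class = "sim_genome")
}

#' Simulate a labelled ncRNA reference set
#'
#' Random references standing in for the snoRNA/tRNA/miRNA/rDNA collections
#' used for read decontamination. Contaminant reads are sampled as exact
#' substrings of these, the worst case for the decontamination filter.
#'
#' @param config A [sim_config()] object.
#' @return data.frame with columns `id`, `class`, `sequence`.
#' @export
sim_ncrna <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 7L)
  spec <- list(snoRNA = list(n = 20L, len = c(70L, 200L)),
               tRNA = list(n = 20L, len = c(70L, 90L)),
               miRNA_hairpin = list(n = 15L, len = c(60L, 90L)),
               miRNA_mature = list(n = 15L, len = c(20L, 23L)),
               rDNA = list(n = 2L, len = c(1500L, 2500L)))
  out <- lapply(names(spec), function(cl) {
    n <- spec[[cl]]$n
    lens <- sample(seq(spec[[cl]]$len[1L], spec[[cl]]$len[2L]), n,
                   replace = TRUE)
    df(id = sprintf("%s_%02d", cl, seq_len(n)), class = cl,
       sequence = vapply(lens, function(L)
         paste(sample(BASES, L, replace = TRUE), collapse = ""), ""))
  })
  do.call(rbind, out)
}

#' Simulate small-RNA reads from a planted genome
#'
#' Per sample, reads are drawn as contaminants (exact ncRNA substrings) or
#' piRNA reads; piRNA reads pick a cluster from the per-sample abundance
#' distribution, then a primary site (a T-start site with probability
#' `u_bias`, so the per-read 5' uridine indicator is i.i.d. Bernoulli) or a
#' secondary site. The insert is an exact genome substring starting at the
#' site's 5' end with a length drawn from `length_distribution`; the 3'
#' adapter is appended and the read padded/truncated to the instrument
#' length.
#'
#' @param config A [sim_config()] object.
#' @param genome A [sim_genome()] object.
#' @param ncrna A [sim_ncrna()] reference data.frame.
#' @return List with `reads` (data.frame `id`, `sequence`, `quality_string`,
#'   `sample`), `truth` (one row per read: origin, cluster, site, insert
#'   length, 1U flag) and `expected_cluster_prob` (cluster x sample matrix of
#'   multinomial origin probabilities for piRNA reads).
#' @export
sim_reads <- function(config, genome, ncrna) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "sim_genome"))
  samples <- config$samples
  n <- config$reads_per_sample
  ilens <- as.integer(names(config$length_distribution))
  alen <- nchar(config$adapter)
  L <- config$read_length
  set.seed(config$seed + 1001L)
  pad_pool <- paste(sample(BASES, 10000L, replace = TRUE), collapse = "")

  prim_sites <- genome$sites[genome$sites$type == "primary", , drop = FALSE]
  sec_sites <- genome$sites[genome$sites$type == "secondary", , drop = FALSE]
  cl_ids <- colnames(genome$multipliers)
  t_by_cl <- split(which(prim_sites$t_start),
                   prim_sites$cluster[prim_sites$t_start])
  nt_by_cl <- split(which(!prim_sites$t_start),
                    prim_sites$cluster[!prim_sites$t_start])
  sec_by_cl <- split(seq_len(nrow(sec_sites)), sec_sites$cluster)
  # forcing collisions can in principle empty a list; fall back to any site
  all_by_cl <- split(seq_len(nrow(prim_sites)), prim_sites$cluster)
  for (cl in cl_ids) {
    if (!length(t_by_cl[[cl]])) t_by_cl[[cl]] <- all_by_cl[[cl]]
    if (!length(nt_by_cl[[cl]])) nt_by_cl[[cl]] <- all_by_cl[[cl]]
  }

  nc_ok <- ncrna[nchar(ncrna$sequence) >= max(ilens), , drop = FALSE]
  if (!nrow(nc_ok)) stopf("no ncRNA reference long enough for contaminants")

  prob_mat <- matrix(0, length(cl_ids), nrow(samples),
                     dimnames = list(cl_ids, samples$sample))
  reads <- vector("list", nrow(samples))
  truths <- vector("list", nrow(samples))

  for (si in seq_len(nrow(samples))) {
    samp <- samples$sample[si]
    cond <- samples$condition[si]
    set.seed(config$seed + 2000L + si)
    p <- genome$cluster_weights * genome$multipliers[cond, ]
    p <- p / sum(p)
    prob_mat[, si] <- p

    is_contam <- stats::runif(n) < config$contaminant_fraction
    is_sec <- !is_contam & stats::runif(n) < config$secondary_fraction
    is_prim <- !is_contam & !is_sec
    ilen <- sample(ilens, n, replace = TRUE,
                   prob = config$length_distribution)
    cluster <- rep(NA_character_, n)
    site_pos <- rep(NA_integer_, n)
    chrom <- rep(NA_character_, n)
    ncrna_class <- rep(NA_character_, n)
    insert <- character(n)

    n_pi <- sum(!is_contam)
    cl_draw <- sample(cl_ids, n_pi, replace = TRUE, prob = p)
    cluster[!is_contam] <- cl_draw

    # primary reads: T site with probability u_bias, per read
    pi_idx <- which(is_prim)
    want_t <- stats::runif(length(pi_idx)) < config$u_bias
    pick <- integer(length(pi_idx))
    for (cl in cl_ids) {
      for (tt in c(TRUE, FALSE)) {
        sel <- which(cluster[pi_idx] == cl & want_t == tt)
        if (!length(sel)) next
        pool <- if (tt) t_by_cl[[cl]] else nt_by_cl[[cl]]
        pick[sel] <- pool[sample.int(length(pool), length(sel),
                                     replace = TRUE)]
      }
    }
    site_pos[pi_idx] <- prim_sites$pos[pick]
    chrom[pi_idx] <- prim_sites$chrom[pick]

    sec_idx <- which(is_sec)
    if (length(sec_idx)) {
      pick_s <- integer(length(sec_idx))
      for (cl in cl_ids) {
        sel <- which(cluster[sec_idx] == cl)
        if (!length(sel)) next
        pool <- sec_by_cl[[cl]]
        if (is.null(pool) || !length(pool)) stopf("cluster %s has no secondary sites", cl)
        pick_s[sel] <- pool[sample.int(length(pool), length(sel),
                                       replace = TRUE)]
      }
      site_pos[sec_idx] <- sec_sites$pos[pick_s]
      chrom[sec_idx] <- sec_sites$chrom[pick_s]
    }

    gi <- which(!is_contam)
    insert[gi] <- substring(genome$genome[chrom[gi]], site_pos[gi] + 1L,
                            site_pos[gi] + ilen[gi])

    ci <- which(is_contam)
    if (length(ci)) {
      ref <- sample.int(nrow(nc_ok), length(ci), replace = TRUE)
      rl <- nchar(nc_ok$sequence[ref])
      st <- floor(stats::runif(length(ci)) * (rl - ilen[ci] + 1L))
      insert[ci] <- substring(nc_ok$sequence[ref], st + 1L, st + ilen[ci])
      ncrna_class[ci] <- nc_ok$class[ref]
    }

    pad_needed <- pmax(0L, L - ilen - alen)
    off <- sample.int(10000L - max(pad_needed), n, replace = TRUE)
    pad <- substring(pad_pool, off, off + pad_needed - 1L)
    seqr <- substr(paste0(insert, config$adapter, pad), 1L, L)

    qual <- strrep(config$quality_char, L)
    if (config$quality_decay > 0) {
      tails <- pmin(stats::rpois(n, config$quality_decay), L - 1L)
      qual <- paste0(strrep(config$quality_char, L - tails),
                     strrep("#", tails))
    }

    ids <- sprintf("%s_read_%06d", samp, seq_len(n))
    reads[[si]] <- df(id = ids, sequence = seqr, quality_string = qual,
                      sample = samp)
    truths[[si]] <- df(id = ids, sample = samp,
                       origin = ifelse(is_contam, "ncrna",
                                       ifelse(is_sec, "secondary", "primary")),
                       cluster = cluster, chrom = chrom, site_pos = site_pos,
                       ncrna_class = ncrna_class, insert_length = ilen,
                       is_1u = startsWith(insert, "T"))
  }

  list(reads = do.call(rbind, reads), truth = do.call(rbind, truths),
       expected_cluster_prob = prob_mat)
}

#' Simulate a knockdown-vs-control expression table
#'
#' Control counts are negative-binomial around log-normal baseline means;
#' in the knockdown condition the means of targeted genes are multiplied by
#' `2^(kd_log2fc + N(0, kd_sd))`, non-targeted genes are unchanged except for
#' counting noise.
#'
#' @param config A [sim_config()] object.
#' @param target_genes Optional character vector of targeted gene ids;
#'   defaults to a random `targeted_fraction` of genes.
#' @return List with `counts` (gene x sample matrix), `conditions` (named
#'   condition vector) and `truth` (per-gene target status and true log2FC).
#' @export
sim_expression <- function(config, target_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 10L) stopf("n_genes must be >= 10")
  if (config$dispersion <= 0) stopf("non-positive dispersion")
  set.seed(config$seed + 5000L)
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  if (is.null(target_genes))
    target_genes <- sample(genes, round(config$targeted_fraction *
                                          config$n_genes))
  is_target <- genes %in% target_genes
  mu <- stats::rlnorm(config$n_genes, config$expr_meanlog, config$expr_sdlog)
  lfc <- ifelse(is_target,
                config$kd_log2fc + stats::rnorm(config$n_genes, 0, config$kd_sd),
                0)
  nr <- config$n_reps_expr
  size <- 1 / config$dispersion
  draw <- function(m) stats::rnbinom(length(m), mu = m, size = size)
  ctrl <- vapply(seq_len(nr), function(i) draw(mu), numeric(config$n_genes))
  kd <- vapply(seq_len(nr), function(i) draw(mu * 2^lfc),
               numeric(config$n_genes))
  counts <- cbind(ctrl, kd)
  dimnames(counts) <- list(genes, c(paste0("control_", seq_len(nr)),
                                    paste0("kd_", seq_len(nr))))
  conditions <- stats::setNames(rep(c("control", "kd"), each = nr),
                                colnames(counts))
  list(counts = counts, conditions = conditions,
       truth = df(gene = genes, is_target = is_target, true_lfc = lfc))
}

#' Simulate a transcriptome with planted piRNA target sites
#'
#' Random transcripts (one per gene) in which targeted genes receive planted
#' piRNA sites: the piRNA sequence itself (sense homology) or its reverse
#' complement (antisense complementarity) substituted into the transcript.
#'
#' @param pirnas data.frame with columns `id`, `sequence` (the piRNA set to
#'   plant from).
#' @param n_genes Number of genes/transcripts.
#' @param target_genes Character vector of gene ids to receive sites;
#'   defaults to the first 20% of genes.
#' @param seed Integer seed.
#' @param mean_sites Mean number of planted sites per targeted gene.
#' @param length_range Transcript length range.
#' @param p_antisense Probability a planted site is antisense.
#' @return List with `transcripts` (`transcript_id`, `gene_id`, `sequence`)
#'   and `truth` (planted site table).
#' @export
sim_transcriptome <- function(pirnas, n_genes = 50L, target_genes = NULL,
                              seed = 1L, mean_sites = 3,
                              length_range = c(500L, 1500L),
                              p_antisense = 0.7) {
  assert_cols(pirnas, c("id", "sequence"))
  set.seed(seed + 9000L)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  if (is.null(target_genes)) genes_t <- genes[seq_len(max(1L, n_genes %/% 5L))]
  else genes_t <- target_genes
  lens <- sample(seq(length_range[1L], length_range[2L]), n_genes,
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), "")
  names(seqs) <- genes
  truth <- list()
  for (g in genes_t) {
    k <- 1L + stats::rpois(1L, max(0, mean_sites - 1))
    pis <- sample(nrow(pirnas), min(k, nrow(pirnas)))
    for (pi_i in pis) {
      pseq <- pirnas$sequence[pi_i]
      anti <- stats::runif(1) < p_antisense
      site <- if (anti) revcomp(pseq) else pseq
      L <- nchar(seqs[[g]])
      if (L < nchar(site) + 2L) next
      at <- sample(L - nchar(site), 1L)
      substr(seqs[[g]], at, at + nchar(site) - 1L) <- site
      truth[[length(truth) + 1L]] <-
        df(gene_id = g, pirna = pirnas$id[pi_i], position = at,
           orientation = if (anti) "antisense" else "sense")
    }
  }
  list(transcripts = df(transcript_id = paste0(genes, "_t1"), gene_id = genes,
                        sequence = unname(seqs)),
       truth = if (length(truth)) do.call(rbind, truth) else
         df(gene_id = character(0), pirna = character(0),
            position = integer(0), orientation = character(0)))
}

#' Write a simulated dataset to disk
#'
#' Emits the genome and reference FASTAs, truth-cluster BED, per-sample
#' FASTQ files, ncRNA reference FASTA and a JSON echo of the configuration.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
sim_write <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- sim_genome(config)
  nc <- sim_ncrna(config)
  rd <- sim_reads(config, g, nc)
  write_fasta(df(id = names(g$genome), sequence = unname(g$genome)),
              file.path(dir, "genome.fa"))
  write_fasta(g$pirna_ref, file.path(dir, "pirna_ref.fa"))
  write_fasta(df(id = paste0(nc$class, "|", nc$id), sequence = nc$sequence),
              file.path(dir, "ncrna.fa"))
  write_bed(g$clusters, file.path(dir, "truth_clusters.bed"))
  write_bed(g$annotations, file.path(dir, "pirna_annotations.bed"))
  for (s in unique(rd$reads$sample)) {
    sub <- rd$reads[rd$reads$sample == s, , drop = FALSE]
    write_fastq(sub, file.path(dir, paste0(s, ".fastq")))
  }
  utils::write.table(rd$truth, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$samples <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(config$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = g, ncrna = nc, reads = rd))
}
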