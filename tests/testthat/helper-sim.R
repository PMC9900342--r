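# Small simulator presets used across unit tests (desk scale; acceptance
# tests use the full defaults). Overrides win over the preset values.
small_sim <- function(seed = 11, ...) {
  preset <- list(seed = seed, genome_size = 40000L, n_chrom = 2L,
                 n_clusters = 4L, reads_per_sample = 2000L,
                 samples = data.frame(sample = c("DIF0_1", "DIF4_1"),
                                      condition = c("DIF0", "DIF4"),
                                      stringsAsFactors = FALSE))
  do.call(sim_config, utils::modifyList(preset, list(...)))
}

small_world <- function(seed = 11, ...) {
  cfg <- small_sim(seed = seed, ...)
  g <- sim_genome(cfg)
  nc <- sim_ncrna(cfg)
  rd <- sim_reads(cfg, g, nc)
  list(cfg = cfg, genome = g, ncrna = nc, reads = rd)
}
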