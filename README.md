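# pirnakit

`pirnakit` is an R package for the computational analysis of
Piwi-interacting RNAs (piRNAs) in small RNA sequencing data from somatic
cells, together with a synthetic-data generator that makes every stage of
the analysis testable against planted ground truth.

piRNAs are 24–35 nt single-stranded small RNAs bound by Piwi-clade
Argonaute proteins. Outside the germline they occur at low abundance, and
identifying them computationally requires a disciplined chain of filters:
adapter and quality trimming, removal of fragments of abundant structural
ncRNAs (snoRNA, tRNA, miRNA, rDNA), zero-mismatch matching against an
annotated piRNA reference set, genome alignment, and merging of overlapping
piRNA loci into clusters — the unit at which piRNA expression is
quantified. Downstream, the package computes the canonical sequence
signatures (read-length spectrum, 5′ uridine bias, and the probability
distribution of 5′–5′ distances between putative primary and secondary
piRNAs, LOWESS-smoothed), tests clusters for differential expression with a
negative-binomial surrogate, and assigns piRNAs to mRNA targets by sense
homology or antisense complementarity, comparing the modulation of target
versus nontarget genes with a two-sample Kolmogorov–Smirnov test.

## The statistics at the core

* **Cluster calling**: overlapping and book-ended piRNA loci are merged
  strand-agnostically (`mergeBed` preset); reads are counted per cluster
  only when fully contained (`intersectBed -f 1`), each placement of a
  multi-mapper counting its full read multiplicity.
* **5′–5′ distance probability**: for each cluster, every same-strand
  (primary, secondary) pair of unique sequences contributes the signed
  distance `d = 5′(secondary) − 5′(primary)` within ±200 nt; per-cluster
  histograms are normalized and averaged, then smoothed by degree-1
  tricube LOWESS with span 0.1. Concentration near d = 0 is the
  co-initiation / ping-pong-like signature.
* **Differential expression**: median-of-ratios size factors, pooled
  method-of-moments NB dispersion, Wald test, Benjamini–Hochberg;
  calls at padj ≤ 0.05 and |log2FC| ≥ 1.
* **Target statistics**: per gene, the number of distinct targeting piRNA
  sequences and their summed TPM; KS comparison of log2 fold changes of
  target vs nontarget genes, with exact enumeration for n₁+n₂ ≤ 20.

All thresholds (trim `-m 25 -q 20`; ncRNA filter identity 80 / mismatches
≤ 1 / coverage ≥ 90; 100-alignment cap; DE padj 0.05, |log2FC| 1; distance
window 200; LOWESS span 0.1; 3 scaled MADs; ANOVA α 0.05) are exposed in a
single JSON-serializable configuration (`default_config()`).

## Worked example

Simulate a small dataset with planted structure and run every stage:

```r
library(pirnakit)

cfg  <- default_config()
scfg <- sim_config(seed = 1, genome_size = 60000, n_chrom = 2,
                   n_clusters = 6, reads_per_sample = 5000)
res  <- run_pipeline(cfg, sim_cfg = scfg, outdir = "example_out")
str(res$summary)
```

Output of this exact run (seed 1):

```
n_reads_raw                30000
n_retained_after_trim      29370
n_removed_ncrna            1486
n_putative_pirnas          27880
n_matched_pirnas           25320
n_clusters                 6
mean_cluster_length        151
mode_read_length           30
distance_argmax_raw        1
distance_argmax_smoothed   1
de_genes_up                16
de_genes_down              1
max_target_load            61
ks_D                       0.9116
ks_p                       2.567e-23
cluster_recall             1
spurious_cluster_rate      0
```

Reading it: of 30,000 simulated reads, 29,370 survive adapter/quality/length
trimming; 1,486 collapsed read records are removed as ncRNA contaminants;
27,880 reads (multiplicity-weighted) remain as putative piRNAs of which
25,320 match the annotated reference with zero mismatches. Merging their
genomic loci recovers exactly the 6 planted clusters (recall 1, no spurious
clusters) with mean length 151 nt. The modal read length is the planted
30 nt, and the 5′–5′ distance profile peaks at +1 both raw and after LOWESS
smoothing — the planted near-zero offset kernel. In the knockdown
comparison, 16 genes are called up and 1 down; targeted genes shift up
relative to nontargets (KS D = 0.91, p ≈ 2.6e-23).

The same pipeline can be driven from the shell:

```sh
Rscript inst/cli/pirnakit simulate --seed 1 --out simdir
Rscript inst/cli/pirnakit run-all --in simdir --out results
```

## Documentation

`vignettes/pirnakit-methods.Rmd` describes the models, every tunable
parameter with its default and provenance, what the synthetic world does
and does not emulate, numerical edge cases, and known limitations.
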