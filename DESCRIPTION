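Package: pirnakit
Title: piRNA Discovery, Characterization and Target Analysis for Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("pirnakit", "developers", email = "pirnakit@example.org",
           role = c("aut", "cre"))
Description: A tested re-usable pipeline for the computational analysis of
    Piwi-interacting RNAs (piRNAs) in somatic small RNA sequencing data:
    adapter/quality trimming and known-ncRNA decontamination, piRNA
    identification by annotated-reference matching, genomic cluster calling by
    merging overlapping piRNA loci, sequence-feature characterization (length
    distribution, 5' uridine bias, primary/secondary 5'-5' distance
    probability with LOWESS smoothing), expression quantification with a
    negative-binomial differential-expression surrogate, and in-silico piRNA
    target assignment with target-versus-nontarget modulation statistics. A
    synthetic-data module generates genomes, annotations and reads with
    planted piRNA structure so that every stage is testable against ground
    truth without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
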