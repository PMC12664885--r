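Package: longemseq
Title: Targeted Long-Read Enzymatic Methyl-Seq Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for haplotype- and variant-resolved CpG methylation
    analysis of base-converted (EM-seq) long reads enriched by
    hybridization capture. Includes dual-index barcode demultiplexing of
    long reads, conversion-aware allele assignment and pseudo-read
    haplotype phasing with switch-error evaluation, per-CpG methylation
    extraction by sample, haplotype or somatic-variant class,
    differential-methylation-region calling with coverage and
    difference-filter cascades, hybridization-capture quality metrics
    (duplicate marking, bait coverage, fold enrichment, on-target rate),
    and a fully specified synthetic-experiment generator that emits
    reference, variants, methylome, reads and complete truth tables so
    every stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
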