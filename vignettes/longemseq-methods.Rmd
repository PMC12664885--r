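---
title: "Conversion-aware analysis of targeted long-read enzymatic methyl-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion-aware analysis of targeted long-read enzymatic methyl-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longemseq)
```

## The problem

Enzymatic methyl sequencing (EM-seq) chemistry converts unmethylated
cytosine to uracil, read as thymine after amplification, while methylated
cytosine is protected. When such converted libraries are sequenced as
long nanopore reads and enriched by hybridization capture, a single read
carries two kinds of signal at once: the methylation state of every CpG
it crosses, and the alleles of every heterozygous SNP it crosses. The
difficulty is that conversion corrupts the SNP signal — in the read
frame where C reads as T, a C/T polymorphism becomes invisible — so
standard phasing and variant-aware tools cannot consume these reads
directly.

`longemseq` implements the computational side of this assay: base
conversion semantics, dual-index demultiplexing of the pooled libraries,
conversion-aware allele assignment and pseudo-read haplotype phasing,
haplotype- and somatic-variant-resolved CpG methylation, differential
methylation region (DMR) calling with the coverage/difference/TSS filter
cascade used for allele-specific methylation screens, capture QC
metrics, and a synthetic-experiment generator with complete truth
tables so the whole pipeline is testable without sequencing data.

## Conversion spaces and the observation model

A double-stranded converted library yields reads in one of two frames
relative to the top-strand reference:

* **CT space** (original top strand): unmethylated `C` is observed as
  `T`; the observation set of a genomic `C` is `{C, T}`.
* **GA space** (original bottom strand): the complementary conversion
  appears as `G` observed as `A`; the observation set of `G` is
  `{G, A}`.

`allele_support(space, ref, alt, observed)` classifies a pileup base as
`REF`, `ALT`, `AMBIGUOUS` (reachable from both alleles — e.g. a `T` over
a C/T SNP in CT space) or `OTHER`. `restore_base()` maps a supported
observation back to its genomic allele and `N` otherwise. Two
conservative choices are deliberate:

* every genomic `C` is treated as possibly methylated whatever its
  context, so the observation set of `C` is always `{C, T}` in CT space
  — EM-seq cannot guarantee a specific non-CpG cytosine is unmethylated;
* `N`, deletions and insertions over a variant are uninformative
  (`OTHER`), matching pileup-style base extraction.

The whole 2 (spaces) x 12 (ordered allele pairs) x 5 (observed bases)
table is locked to a brute-force enumeration of conversion outcomes in
the test suite, together with the strand-symmetry identity
`support_GA(ref, alt, obs) = support_CT(comp ref, comp alt, comp obs)`.

One consequence, inherited from the chemistry, is that C/T and G/A
variants are each resolvable in only one of the two frames, so roughly
half the reads are uninformative at such sites. The simulator offers a
`distinguishable_only` mode to quantify this.

## Pseudo-read phasing

Phasing consumes only primary alignments (complex structural variants
present as primary + supplementary combinations, so excluding
supplementary records keeps them out). For every read x het-SNP cell the
allele matrix stores the conversion-aware support; `make_pseudo_reads()`
then emits coordinate-preserving reads that carry the restored allele at
informative sites and `N` everywhere else. These pseudo reads are
exportable as SAM (single-`M` CIGAR over the original span) so an
external read-backed phaser can be used in their place; the built-in
phaser is a greedy maximum-weight spanning forest over the variant
linkage graph:

* each read covering an informative variant pair adds a *cis* (same
  support) or *trans* (opposite) observation;
* edge weight is `|cis - trans|`, orientation `sign(cis - trans)`;
  edges below `min_link = 2` net observations are dropped, because a
  single 1%-error read is too weak to link two SNPs;
* each spanning tree is one phased block; haplotype bits propagate from
  an arbitrary root, so phase is relative within a block (all reported
  accuracies and the switch error are flip-invariant).

On error-free instances the forest attains the minimum-error-correction
optimum (checked against an exhaustive `2^(v-1)` oracle on small cases).
`haplotag_reads()` assigns each read to the haplotype matching the
majority of its informative phased sites with margin at least one site;
ties and reads below `min_sites` stay untagged. When blocks are short, a
`WITH_UNPHASED_SNPS` mode additionally partitions reads at singleton het
SNPs into per-site allele groups. `classify_by_snv()` applies the same
machinery to somatic SNVs: any informative ALT makes a read
`SNV_PLUS`, consistent REF support makes it `SNV_MINUS` — deliberately
independent of allele frequency, so low-cellularity tumour alleles are
collected rather than averaged away.

Switch error is measured over consecutive variant pairs phased in both
test and truth within single blocks; block N50 is computed over block
genomic spans.

## Methylation calling and DMRs

`call_cpg_methylation()` destrands CpG evidence: CT-space reads vote
through the base over the `C` (`C` methylated, `T` unmethylated), GA
reads through the base over the paired `G` (`G`/`A`), and both collapse
into one record keyed by the C position. CpGs whose C or G coincides
with a variant are dropped — a genotype difference would masquerade as a
methylation difference. Duplicates and non-primary records never vote.
The MAPQ floor defaults to 20 and no base-quality filter is applied;
both are options, not claims about any particular upstream pipeline.

`call_dmrs()` works on coverage-filtered tables (`coverage_filter()`
keeps CpGs where *every* compared group reaches the floor; five reads
for sample comparisons, three for allele-resolved comparisons, where
each haplotype carries about half the depth):

1. shared CpGs are pre-segmented into runs at gaps over `max_gap`
   (300 bp);
2. within a run, the candidate window is seeded at the contiguous
   stretch of at least `min_cpgs` (10) CpGs maximizing the absolute mean
   group difference, then extended outward while adjacent per-CpG
   differences keep the same sign and at least `min_diff` (0.1)
   magnitude — the extension step is what lands boundaries where the
   signal decays instead of on the noisiest core, and is why recovered
   boundaries sit within a few CpGs of planted ones;
3. the window is tested with a two-sided Mann-Whitney U on the two
   per-CpG rate vectors (exact for small untied samples; normal
   approximation with tie correction otherwise, since rates tie heavily
   at 0 and 1), removed, and the flanks are re-scanned;
4. Benjamini-Hochberg adjustment is applied genome-wide across all
   extracted windows, and regions with `q < 0.01` are reported.

Degenerate constant windows get `p = 1` by convention and are never
reported. Difference filters are absolute (unsigned) by default — the
direction of an allele difference is arbitrary under relative phase —
and configurable. The greedy selection step biases the p-value of the
selected window downward; the `min_diff` gate plus genome-wide BH keeps
the practical false-call rate in check, which is asserted empirically
(200 same-distribution candidate runs must yield any `q < 0.01` call in
at most 5% of runs at 25-30x coverage). This is a calibration property
of the whole procedure, not an exactness claim about the selected
window's p-value.

Downstream, `merge_dmrs()` unions per-sample DMR sets and re-averages
per-CpG rates above the coverage floor within each merged interval
(groups without a passing CpG are flagged not measurable);
`apply_filter_cascade()` evaluates difference predicates (any-pair or
named-pair, with lower and/or upper thresholds) and optionally requires
measurability in all samples; `annotate_tss()` computes the
interval-to-TSS gap (0 when the TSS is inside; strand-ignored, the
window is symmetric) and flags intervals within the +-10 kb window.

## Capture QC

`mark_duplicates()` keys on (chromosome, orientation, unclipped 5'
start) — the common single-end convention — with an optional
end-aware mode with tolerance for long-read 3' jitter; the
representative is the longest aligned span, ties broken by read id, so
re-marking is idempotent. `hs_metrics()` fixes the formulas explicitly:
mean bait coverage is on-target aligned bases over target territory and
fold enrichment is the on-target base fraction normalized by the
territory's share of the genome; aligned bases are CIGAR `M`/`=`/`X`
bases, clips never count, and the mapped-read denominator excludes
secondary and supplementary records. The overlap rate counts reads
intersecting a target by at least one base, reported with and without
duplicates. Both metrics are locked to a per-base brute-force oracle on
small instances. `read_length_stats()` reports the base-weighted N50.

## The simulator

`sim_config()` holds the full generative model; the defaults are the
study conditions everything else is tested under:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 5 Mb | single synthetic chromosome |
| `n_targets`, `target_length` | 40 x 6 kb | capture intervals, evenly spaced |
| `island_length` | 1.5 kb | CpG island centred in each target |
| `gc_content` / `cpg_depletion` | 0.41 / 0.7 | background GC; fraction of background CpGs mutated away |
| `het_snp_rate` | 1/1500 bp | Poisson het-SNP density, random phase |
| `fragment_n50`, `fragment_sigma` | 5 kb, 0.55 | lognormal fragments (N50 is the base-weighted median) |
| `coverage` | 30x | mean genome-wide depth |
| `p_on_target` | 0.9 | capture enrichment |
| `duplicate_rate` | 0.1 | PCR duplicates sharing the converted template |
| `conversion_efficiency` | 0.995 | unmethylated C converted |
| `over_conversion_rate` | 0.005 | methylated C converted anyway |
| `sub/ins/del_rate` | 1% / 0.5% / 0.5% | nanopore-like iid errors |
| `vaf` | 0.3 | somatic SNV allele fraction (one haplotype, cellularity 2 x VAF) |

Conversion efficiency and over-conversion follow typical EM-seq QC
practice; they are parameters, not claims. Methylation is drawn
*per molecule per CpG* from the molecule's probability vector (island
CpGs Beta(1,10), background Beta(10,1), overwritten inside planted ASM /
group-DMR / SNV-linked regions), so allele- and carrier-specific
patterns are coherent along a whole fragment, which is exactly the
property long reads exploit. Truth alignments are written against the
untransformed reference with indel-consistent CIGARs and the conversion
frame in an `XC` tag, so every downstream stage runs without an aligner.
Every draw is fixed by the seed; identical configs are byte-identical on
disk.

What the simulator does *not* model — and what green tests therefore do
not certify about real data: alignment and mapping error (truth
coordinates are used), basecaller-specific error profiles (errors are
iid), PCR chimeras, hemimethylation (both strands of a molecule share
one CpG state), probe-proximal off-target structure (off-target starts
are uniform), GC bias, and aneuploidy. Switch-error rates measured on
real samples include exactly such artifacts (and errors in whatever
comparison phasing they are scored against), which is why the
simulated benchmark is expected to come in below rates achievable on
tissue.

## Problem sizes used by the checks

The acceptance benchmarks run the full 5 Mb / 30x / 5 kb-N50 phasing
condition (about 35,000 reads, 3,300 het SNPs, 1,700 comparable adjacent
pairs) and a 10,000-read demultiplexing condition; both complete in
about a minute of CPU. Unit and property tests use 0.1-1 Mb genomes so
the whole suite stays inside a few minutes. DMR calibration uses 200
candidate runs at coverage 25; recovery uses 20 planted regions of 15-25
CpGs at coverage 25 with differences 0.5-0.8.

## Numerical and design choices

* **Coordinates** are 1-based inclusive internally (the R/Bioconductor
  convention); BED and bedGraph writers convert to 0-based half-open at
  the boundary.
* **Tie-breaks**: duplicate representatives by longest span then read
  id; barcode hits by lowest edit distance then position; `cis == trans`
  linkage edges are dropped rather than oriented arbitrarily; haplotag
  ties are untagged rather than guessed.
* **Degenerate inputs**: empty FASTQ yields a zero-count report; zero
  aligned bases yields zero metrics with a warning; phasings with no
  comparable pairs report a missing switch error with `n = 0` rather
  than 0.
* **classify_read_space** (used only when alignments carry no
  conversion tag) demands at least 10 conversion-consistent mismatches
  and an 80% majority before committing; a 5 kb converted read carries
  hundreds of conversion events, so these thresholds are generous.
* **Barcode matching** uses unit-cost edit distance (substitutions and
  indels) with an exact-match fast path; the default tolerance of 1 for
  8-mers trades nanopore error against collision risk, and the sheet
  loader warns when any inter-barcode distance is within twice the
  tolerance.

## Known limitations

* The DMR caller is a defined replacement for segmentation tools of its
  class, not a bit-for-bit reimplementation of any of them; its
  boundaries and p-values will differ from other callers on the same
  input even though thresholds and interface match.
* The internal phaser is a heuristic; on noisy instances it is not
  guaranteed MEC-optimal (the optimality property is asserted on
  consistent instances). The pseudo-read SAM / phased VCF interface
  exists precisely so a dedicated phaser can be substituted.
* Genome-wide SNV pooling merges all carrier molecules; the per-locus
  mode should be preferred when several unrelated somatic events fall in
  one capture target.
* Switch-error measurement requires a truth (or comparison) phasing over
  the same variant set; with real data its quality bounds what the
  metric can show.
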