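# Annotated example configuration for `longemseq run` / run_pipeline().
#
# Either provide real inputs (alignments + reference [+ targets, VCFs,
# tss]) or a `simulate` block; with `simulate`, inputs are generated
# under <out_dir>/sim and the truth tables are kept alongside.

mode: HAPLOTYPE_DMR      # SAMPLE_DMR | HAPLOTYPE_DMR | SNV_DMR
seed: 1
out_dir: longemseq_run

# --- provided inputs (unused when `simulate` is present) -------------
# alignments: aligned_converted_reads.sam   # XC tag trusted if present
# reference:  reference.fa
# targets:    capture_targets.bed
# het_vcf:    het_snps.vcf                  # phased GT|PS honoured
# snv_vcf:    somatic_snvs.vcf
# tss:        tss.tsv                       # gene, chrom, pos, strand

# --- synthetic experiment (sim_config overrides) ---------------------
simulate:
  genome_length: 500000
  n_targets: 8
  coverage: 25
  fragment_n50: 4000
  n_asm: 3                # planted allele-specific methylation regions
  n_somatic_snvs: 0

# --- stage parameters (defaults shown) -------------------------------
phasing:
  min_link: 2             # min |cis - trans| read support per edge
  min_sites: 1            # informative phased sites per tagged read
  haplotag_mode: WITH_UNPHASED_SNPS
methylation:
  min_mapq: 20
dmr:
  max_gap: 300            # bp; CpG runs split at larger gaps
  min_cpgs: 10
  min_diff: 0.1
  q_cut: 0.01
  # min_cov: null         # default: 5 in SAMPLE_DMR mode, 3 otherwise
  filter_min_diff: 0.5    # any-pair difference rule on merged DMRs
  tss_window: 10000       # bp, symmetric
qc:
  enabled: true
  use_end: false          # duplicate key: add 3' end
  end_tolerance: 0
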