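small_cfg <- function(...) {
  sim_config(seed = 81, genome_length = 2e5, n_targets = 4,
             coverage = 10, fragment_n50 = 2000, min_fragment = 400,
             n_somatic_snvs = 5, n_asm = 2, ...)
}

test_that("config validation reports all violations together", {
  expect_error(sim_config(p_on_target = 1.5, sub_rate = -1),
               "p_on_target.*\n.*sub_rate")
  expect_error(sim_config(unknown_knob = 1), "unknown")
  expect_error(sim_config(genome_length = 1e4, n_targets = 10,
                          target_length = 2000), "exceed")
  expect_error(sim_config(vaf = 0.8), "vaf")
})

test_that("reference simulation is deterministic and island-enriched", {
  cfg <- small_cfg()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(as.character(r1$reference), as.character(r2$reference))
  # byte-identical FASTA on disk
  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeXStringSet(r1$reference, f1)
  Biostrings::writeXStringSet(r2$reference, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  # CpG density inside islands > 3x background
  cpg <- GenomicRanges::GRanges(r1$cpg$chrom,
                                IRanges::IRanges(r1$cpg$pos, width = 2))
  in_isl <- sum(IRanges::overlapsAny(cpg, r1$islands))
  isl_bp <- sum(BiocGenerics::width(r1$islands))
  bg_bp <- cfg$genome_length - isl_bp
  dens_in <- in_isl / isl_bp
  dens_out <- (nrow(r1$cpg) - in_isl) / bg_bp
  expect_gt(dens_in, 3 * dens_out)
  # zero targets: valid genome, empty target set
  r0 <- simulate_reference(small_cfg(n_targets = 0L))
  expect_identical(length(r0$targets), 0L)
  expect_identical(Biostrings::width(r0$reference)[[1]], 2e5L)
})

test_that("variant counts and patterns follow the configuration", {
  cfg <- sim_config(seed = 82, genome_length = 1e6, n_targets = 4,
                    het_snp_rate = 1 / 1500, n_somatic_snvs = 10)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  lambda <- 1e6 / 1500
  expect_lt(abs(nrow(v$snps) - lambda), 4 * sqrt(lambda))
  expect_false(anyDuplicated(c(v$snps$pos, v$snvs$pos)) > 0)
  # ref alleles match the genome
  refstr <- as.character(ref$reference[[1]])
  expect_identical(substring(refstr, v$snps$pos, v$snps$pos), v$snps$ref)
  # SNVs sit inside targets
  sg <- GenomicRanges::GRanges(v$snvs$chrom,
                               IRanges::IRanges(v$snvs$pos, width = 1))
  expect_true(all(IRanges::overlapsAny(sg, ref$targets)))
  # distinguishable-only mode bans conversion-collapsed pairs
  vd <- simulate_variants(sim_config(seed = 82, genome_length = 1e6,
                                     n_targets = 4,
                                     distinguishable_only = TRUE), ref)
  pairs <- paste(vd$snps$ref, vd$snps$alt)
  expect_false(any(pairs %in% c("C T", "T C", "G A", "A G")))
  for (k in seq_len(nrow(vd$snps))) {
    expect_false(allele_support("CT", vd$snps$ref[k], vd$snps$alt[k],
                                convert_base(vd$snps$ref[k], "CT",
                                             FALSE)) == "AMBIGUOUS")
    expect_false(allele_support("GA", vd$snps$ref[k], vd$snps$alt[k],
                                convert_base(vd$snps$ref[k], "GA",
                                             FALSE)) == "AMBIGUOUS")
  }
})

test_that("methylome plants create the configured allele contrast", {
  cfg <- small_cfg(asm_diff = 0.8)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  me <- simulate_methylome(cfg, ref, v)
  asm <- me$plants[me$plants$type == "ASM", ]
  expect_identical(nrow(asm), 2L)
  for (k in seq_len(nrow(asm))) {
    i <- me$cpg$pos >= asm$start[k] & me$cpg$pos <= asm$end[k]
    d <- abs(mean(me$cpg$p_h1[i]) - mean(me$cpg$p_h2[i]))
    expect_gt(d, 0.75); expect_lt(d, 0.85)
  }
  # without plants the two haplotype tables are identical
  me0 <- simulate_methylome(small_cfg(n_asm = 0L), ref, v)
  expect_identical(me0$cpg$p_h1, me0$cpg$p_h2)
  # same seed, same table
  me2 <- simulate_methylome(cfg, ref, v)
  expect_identical(me$cpg, me2$cpg)
  # islands are mostly unmethylated, background mostly methylated
  expect_lt(mean(me$cpg$p_h1[me$cpg$island &
                               !overlaps_plants(me$cpg$pos, me$plants)]),
            0.2)
  expect_gt(mean(me$cpg$p_h1[!me$cpg$island]), 0.8)
})

test_that("library output is internally consistent", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  me <- simulate_methylome(cfg, ref, v)
  lib <- simulate_library(cfg, ref, v, me)
  # conservation: one truth record per emitted read, in both streams
  expect_identical(nrow(lib$reads), nrow(lib$alignments))
  expect_identical(nrow(lib$reads), nrow(lib$fastq))
  expect_identical(sort(lib$reads$read_id), sort(lib$fastq$id))
  # duplicate links point at an emitted representative, acyclically
  dups <- lib$reads[!is.na(lib$reads$duplicate_of), ]
  expect_true(all(dups$duplicate_of %in% lib$reads$read_id))
  reps <- lib$reads$read_id[is.na(lib$reads$duplicate_of)]
  expect_true(all(dups$duplicate_of %in% reps))
  # CIGAR consumes exactly the read length
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    lib$alignments$cigar)
  expect_identical(qlen, nchar(lib$alignments$seq))
  # determinism end to end
  lib2 <- simulate_library(cfg, ref, v, me)
  expect_identical(lib$alignments$seq, lib2$alignments$seq)
  expect_identical(lib$fastq$seq, lib2$fastq$seq)
})

test_that("VAF controls carrier fraction; zero VAF means no carriers", {
  cfg <- small_cfg(vaf = 0, n_somatic_snvs = 5L)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  me <- simulate_methylome(cfg, ref, v)
  lib <- simulate_library(cfg, ref, v, me)
  expect_false(any(lib$reads$snv_carrier))
  # at VAF 0.3, carriers among covering molecules are near 30%
  cfg3 <- small_cfg(vaf = 0.3, n_somatic_snvs = 10L, coverage = 20)
  v3 <- simulate_variants(cfg3, ref)
  me3 <- simulate_methylome(cfg3, ref, v3)
  lib3 <- simulate_library(cfg3, ref, v3, me3)
  reads <- lib3$reads[is.na(lib3$reads$duplicate_of), ]
  cover <- outer(reads$frag_start, v3$snvs$pos, `<=`) &
    outer(reads$frag_end, v3$snvs$pos, `>=`)
  carried <- merge(lib3$carried_snvs,
                   data.frame(molecule = reads$molecule,
                              row = seq_len(nrow(reads))))
  n_cover <- sum(cover)
  n_carry <- nrow(unique(carried[, c("molecule", "snv_pos")]))
  expect_lt(abs(n_carry / n_cover - 0.3), 3 * sqrt(0.3 * 0.7 / n_cover))
})

test_that("conversion is exhaustive at efficiency 1", {
  cfg <- small_cfg(conversion_efficiency = 1, over_conversion_rate = 0,
                   sub_rate = 0, ins_rate = 0, del_rate = 0,
                   duplicate_rate = 0, het_snp_rate = 0,
                   n_somatic_snvs = 0L, n_asm = 0L)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  me <- simulate_methylome(cfg, ref, v)
  lib <- simulate_library(cfg, ref, v, me)
  refstr <- as.character(ref$reference[[1]])
  cpg_pos <- me$cpg$pos
  ct <- which(lib$alignments$space == "CT")[1:20]
  for (i in ct) {
    a <- lib$alignments[i, ]
    span <- a$pos:(a$pos + nchar(a$seq) - 1L)
    ref_ch <- strsplit(substring(refstr, min(span), max(span)),
                       "")[[1]]
    read_ch <- strsplit(a$seq, "")[[1]]
    is_c <- ref_ch == "C"
    is_cpg <- span %in% cpg_pos
    # every non-CpG C reads as T; CpG Cs read C or T by molecule state
    expect_true(all(read_ch[is_c & !is_cpg] == "T"))
    expect_true(all(read_ch[is_c & is_cpg] %in% c("C", "T")))
    # all other bases untouched
    expect_identical(read_ch[!is_c], ref_ch[!is_c])
  }
})

test_that("read length N50 lands within 10% of the target", {
  cfg <- sim_config(seed = 83, genome_length = 1e6, n_targets = 4,
                    n_reads = 6000, fragment_n50 = 5000,
                    sub_rate = 0, ins_rate = 0, del_rate = 0,
                    n_somatic_snvs = 0L, n_asm = 0L)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  lib <- simulate_library(cfg, ref, v, simulate_methylome(cfg, ref, v))
  n50_obs <- n50(nchar(lib$alignments$seq))
  expect_lt(abs(n50_obs - 5000) / 5000, 0.1)
})

test_that("simulate_experiment writes a coherent artifact set", {
  out <- file.path(tempdir(), "simexp")
  cfg <- small_cfg(store_cpg_truth = FALSE)
  sim <- simulate_experiment(cfg, out)
  expect_true(all(file.exists(sim$files)))
  # SAM round trip preserves the alignment set
  aln <- read_alignments(sim$files[["truth_sam"]])
  expect_identical(nrow(aln), nrow(sim$library$alignments))
  expect_setequal(aln$space, c("CT", "GA"))
  # VCF round trip preserves variants and phase
  het <- read_variants_vcf(sim$files[["het_vcf"]])
  expect_identical(het$pos, sim$variants$snps$pos)
  ph <- attr(het, "phase")
  expect_identical(ph$hap1_is_alt, sim$variants$snps$hap1_is_alt)
  snv <- read_variants_vcf(sim$files[["snv_vcf"]], "SOMATIC_SNV")
  expect_identical(snv$pos, sim$variants$snvs$pos)
  # targets BED round trip
  tg <- read_targets(sim$files[["targets"]])
  expect_identical(BiocGenerics::start(tg),
                   BiocGenerics::start(sim$reference$targets))
  unlink(out, recursive = TRUE)
})
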