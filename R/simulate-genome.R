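#' Default configuration for a synthetic targeted EM-seq experiment
#'
#' Returns the fully-defaulted parameter list the simulator runs from.
#' Defaults describe a capture-enriched long-read EM-seq experiment: a
#' 5 Mb genome with CpG-island-centred capture targets, heterozygous SNPs
#' at one per 1,500 bp, lognormal fragment lengths with a 5 kb N50,
#' strong on-target enrichment, enzymatic conversion efficiency 0.995
#' with 0.005 over-conversion, and nanopore-like error rates (1%
#' substitutions, 0.5% insertions, 0.5% deletions).
#'
#' @param ... Named overrides of any default.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # genome geometry
    genome_length = 5e6, chrom_name = "sim1",
    n_targets = 40L, target_length = 6000L, island_length = 1500L,
    gc_content = 0.41, island_gc = 0.55,
    cpg_depletion = 0.7,      # background CG dinucleotides mutated away
    island_cpg_density = 0.08,  # planted CGs per island bp
    # variants
    het_snp_rate = 1 / 1500, n_somatic_snvs = 20L, vaf = 0.3,
    distinguishable_only = FALSE,
    # methylome
    n_asm = 8L, asm_diff = 0.8,
    n_group_dmr = 0L, group_diff = 0.8,
    n_snv_dmr = 0L, snv_dmr_diff = 0.8,
    # library
    coverage = 30, n_reads = NULL,
    fragment_n50 = 5000, fragment_sigma = 0.55, min_fragment = 500,
    p_on_target = 0.9, duplicate_rate = 0.1,
    conversion_efficiency = 0.995, over_conversion_rate = 0.005,
    sub_rate = 0.01, ins_rate = 0.005, del_rate = 0.005,
    samples = "S1",
    sheet = NULL,             # sample sheet enables multiplex FASTQ
    index_hop_rate = 0,
    store_cpg_truth = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  validate_sim_config(cfg)
}

#' Validate a simulator configuration
#' @param cfg A list of simulator parameters.
#' @return The config, classed `sim_config`; errors list all violations.
#' @export
validate_sim_config <- function(cfg) {
  errs <- character(0)
  frac <- c("gc_content", "island_gc", "cpg_depletion", "p_on_target",
            "duplicate_rate", "conversion_efficiency",
            "over_conversion_rate", "sub_rate", "ins_rate", "del_rate",
            "vaf", "index_hop_rate", "asm_diff", "group_diff",
            "snv_dmr_diff", "het_snp_rate")
  for (f in frac) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
      errs <- c(errs, paste0(f, " must be a fraction in [0, 1]"))
    }
  }
  if (cfg$vaf > 0.5) errs <- c(errs, "vaf must be <= 0.5 (diploid)")
  pos <- c("genome_length", "n_targets", "target_length",
           "island_length", "fragment_n50", "fragment_sigma",
           "min_fragment", "coverage", "seed")
  for (f in pos) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0) {
      errs <- c(errs, paste0(f, " must be non-negative"))
    }
  }
  if (with(cfg, n_targets * target_length >= genome_length)) {
    errs <- c(errs, "targets exceed genome length")
  }
  if (with(cfg, island_length > target_length)) {
    errs <- c(errs, "island_length exceeds target_length")
  }
  if (with(cfg, genome_length < 10 * fragment_n50)) {
    errs <- c(errs, "genome_length must be >= 10x fragment_n50")
  }
  if (!is.null(cfg$sheet)) {
    if (!identical(sort(cfg$sheet$sample_id), sort(cfg$samples))) {
      errs <- c(errs, "sheet sample_ids must match cfg$samples")
    }
  }
  if (length(errs)) {
    stop("invalid sim_config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

.rand_bases <- function(n, gc) {
  codes <- charToRaw("ACGT")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  as.raw(codes[sample.int(4L, n, replace = TRUE, prob = p)])
}

#' Simulate a capture-target reference genome
#'
#' Generates a random background genome at the configured GC content with
#' evolutionary CpG depletion (a fraction of background CG dinucleotides
#' mutated), then plants CpG islands (dense CG dinucleotides at elevated
#' GC) centred inside evenly spaced capture-target intervals.  Each
#' island is given a synthetic gene whose TSS sits at the island start,
#' providing an annotation set for TSS-proximity filtering.
#'
#' @param cfg A [sim_config()].
#' @return list: `reference` ([Biostrings::DNAStringSet]), `targets` and
#'   `islands` (`GRanges`), `cpg` (data.frame of all reference CpGs),
#'   `tss` (data.frame `gene`, `chrom`, `pos`, `strand`).
#' @export
simulate_reference <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  L <- as.integer(cfg$genome_length)
  g <- .rand_bases(L, cfg$gc_content)
  # CpG depletion of the background: mutate the C of most CG dinucs
  C <- charToRaw("C")[1]; G <- charToRaw("G")[1]
  cg <- which(g[-L] == C & g[-1] == G)
  kill <- cg[runif(length(cg)) < cfg$cpg_depletion]
  g[kill] <- charToRaw("T")[1]
  targets <- islands <- NULL
  if (cfg$n_targets > 0) {
    spacing <- L / (cfg$n_targets + 1)
    centers <- round(spacing * seq_len(cfg$n_targets))
    t_start <- pmax(1L, as.integer(centers - cfg$target_length %/% 2))
    t_end <- pmin(L, t_start + as.integer(cfg$target_length) - 1L)
    i_start <- as.integer(centers - cfg$island_length %/% 2)
    i_end <- i_start + as.integer(cfg$island_length) - 1L
    for (k in seq_along(centers)) {
      len <- i_end[k] - i_start[k] + 1L
      isl <- .rand_bases(len, cfg$island_gc)
      n_cg <- round(len * cfg$island_cpg_density)
      at <- sort(sample.int(len - 1L, n_cg))
      at <- at[c(TRUE, diff(at) > 1L)]   # no overlapping CG plants
      isl[at] <- C; isl[at + 1L] <- G
      g[i_start[k]:i_end[k]] <- isl
    }
    targets <- GenomicRanges::reduce(GenomicRanges::GRanges(
      cfg$chrom_name, IRanges::IRanges(t_start, t_end)))
    islands <- GenomicRanges::GRanges(
      cfg$chrom_name, IRanges::IRanges(i_start, i_end))
  } else {
    targets <- GenomicRanges::GRanges()
    islands <- GenomicRanges::GRanges()
  }
  reference <- Biostrings::DNAStringSet(setNames(rawToChar(g),
                                                 cfg$chrom_name))
  cpg <- find_cpg_sites(reference)
  tss <- if (length(islands)) {
    data.frame(gene = sprintf("GENE%03d", seq_along(islands)),
               chrom = cfg$chrom_name,
               pos = BiocGenerics::start(islands),
               strand = rep(c("+", "-"),
                            length.out = length(islands)))
  } else {
    data.frame(gene = character(0), chrom = character(0),
               pos = integer(0), strand = character(0))
  }
  list(reference = reference, targets = targets, islands = islands,
       cpg = cpg, tss = tss)
}

.ALLOWED_ALTS <- list(
  A = c("C", "T"), C = c("A", "G"), G = c("C", "T"), T = c("A", "G")
)

#' Simulate phased heterozygous SNPs and somatic SNVs
#'
#' Heterozygous SNPs are dropped on the genome by a Poisson process at
#' the configured rate, each with a uniform alternate allele and a random
#' phase bit (which haplotype carries the alternate).  Somatic SNVs are
#' placed inside capture targets, assigned to one haplotype, and carried
#' by molecules of that haplotype at a cellularity of `2 * vaf` so the
#' overall variant allele fraction equals `vaf`.  With
#' `distinguishable_only`, C/T and G/A substitutions — whose alleles the
#' base conversion collapses in one read frame — are excluded.
#'
#' @param cfg A [sim_config()].
#' @param refobj Result of [simulate_reference()].
#' @return list: `snps` (`chrom`, `pos`, `ref`, `alt`, `hap1_is_alt`),
#'   `snvs` (`chrom`, `pos`, `ref`, `alt`, `hap`, `vaf`).
#' @export
simulate_variants <- function(cfg, refobj) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  L <- as.integer(cfg$genome_length)
  refstr <- as.character(refobj$reference[[cfg$chrom_name]])
  n_snp <- rpois(1, L * cfg$het_snp_rate)
  pos <- sort(sample.int(L - 1L, min(n_snp, L - 1L)))
  ref <- if (length(pos)) substring(refstr, pos, pos) else character(0)
  alt <- vapply(ref, function(r) {
    pool <- if (cfg$distinguishable_only) .ALLOWED_ALTS[[r]] else {
      setdiff(c("A", "C", "G", "T"), r)
    }
    sample(pool, 1)
  }, character(1), USE.NAMES = FALSE)
  snps <- data.frame(chrom = rep(cfg$chrom_name, length(pos)),
                     pos = pos, ref = ref, alt = alt,
                     hap1_is_alt = rbinom(length(pos), 1, 0.5),
                     stringsAsFactors = FALSE)
  snvs <- data.frame(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     hap = integer(0), vaf = numeric(0))
  if (cfg$n_somatic_snvs > 0 && length(refobj$targets)) {
    tpos <- unlist(mapply(seq,
                          BiocGenerics::start(refobj$targets),
                          BiocGenerics::end(refobj$targets) - 1L,
                          SIMPLIFY = FALSE))
    tpos <- setdiff(tpos, snps$pos)
    vpos <- sort(sample(tpos, min(cfg$n_somatic_snvs, length(tpos))))
    vref <- substring(refstr, vpos, vpos)
    valt <- vapply(vref, function(r) {
      pool <- if (cfg$distinguishable_only) .ALLOWED_ALTS[[r]] else {
        setdiff(c("A", "C", "G", "T"), r)
      }
      sample(pool, 1)
    }, character(1), USE.NAMES = FALSE)
    snvs <- data.frame(chrom = cfg$chrom_name, pos = vpos, ref = vref,
                       alt = valt,
                       hap = sample(1:2, length(vpos), replace = TRUE),
                       vaf = cfg$vaf, stringsAsFactors = FALSE)
  }
  list(snps = snps, snvs = snvs)
}

#' Simulate the per-haplotype CpG methylome
#'
#' Builds the two haplotype genomes (SNP alleles applied), finds their
#' CpGs, and assigns per-CpG methylation probabilities: island CpGs are
#' mostly unmethylated (Beta(1, 10)), background CpGs mostly methylated
#' (Beta(10, 1)).  Planted phenomena overwrite the baseline: ASM regions
#' give the two haplotypes strongly separated probabilities
#' (Beta(45, 5) vs Beta(5, 45), mean difference 0.8); group-DMR regions
#' separate samples; SNV-linked regions separate carrier from
#' non-carrier molecules (the non-carrier level is the baseline).
#' Plants occupy distinct islands and never overlap.
#'
#' @param cfg A [sim_config()].
#' @param refobj From [simulate_reference()].
#' @param variants From [simulate_variants()].
#' @return list: `hap_genomes` (length-2 character), `cpg`
#'   (`pos`, `island`, `p_h1`, `p_h2`, per-CpG presence flags per
#'   haplotype), `plants` (data.frame of planted regions with types
#'   `ASM`, `GROUP`, `SNV`), `group_levels`, `snv_plants`.
#' @export
simulate_methylome <- function(cfg, refobj, variants) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  refstr <- as.character(refobj$reference[[cfg$chrom_name]])
  snps <- variants$snps
  hap_base <- list(
    ifelse(snps$hap1_is_alt == 1L, snps$alt, snps$ref),
    ifelse(snps$hap1_is_alt == 1L, snps$ref, snps$alt)
  )
  hap_genomes <- vapply(1:2, function(h) {
    s <- refstr
    if (nrow(snps)) {
      ch <- hap_base[[h]]
      # vectorised single-base replacement
      raw <- charToRaw(s)
      raw[snps$pos] <- charToRaw(paste(ch, collapse = ""))
      s <- rawToChar(raw)
    }
    s
  }, character(1))
  cpg_of <- function(s) {
    m <- Biostrings::matchPattern("CG", Biostrings::DNAString(s))
    BiocGenerics::start(m)
  }
  cpos <- lapply(hap_genomes, cpg_of)
  allpos <- sort(unique(c(cpos[[1]], cpos[[2]])))
  island <- IRanges::overlapsAny(
    IRanges::IRanges(allpos, width = 2L),
    IRanges::ranges(refobj$islands))
  p_base <- ifelse(island, rbeta(length(allpos), 1, 10),
                   rbeta(length(allpos), 10, 1))
  cpg <- data.frame(pos = allpos, island = island,
                    in_h1 = allpos %in% cpos[[1]],
                    in_h2 = allpos %in% cpos[[2]],
                    p_h1 = p_base, p_h2 = p_base)
  # --- plants ---------------------------------------------------------
  isl <- refobj$islands
  n_isl <- length(isl)
  need <- cfg$n_asm + cfg$n_group_dmr
  if (need > n_isl) stop("not enough islands for the requested plants",
                         call. = FALSE)
  pick <- sample.int(n_isl, need)
  plants <- data.frame(type = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       hi_hap = integer(0), stringsAsFactors = FALSE)
  hi_draw <- function(n) rbeta(n, 45, 5)
  lo_draw <- function(n) rbeta(n, 5, 45)
  if (cfg$n_asm > 0) for (i in pick[seq_len(cfg$n_asm)]) {
    st <- BiocGenerics::start(isl[i]); en <- BiocGenerics::end(isl[i])
    in_r <- cpg$pos >= st & cpg$pos <= en
    hi_hap <- sample(1:2, 1)
    hi <- hi_draw(sum(in_r)); lo <- lo_draw(sum(in_r))
    cpg$p_h1[in_r] <- if (hi_hap == 1L) hi else lo
    cpg$p_h2[in_r] <- if (hi_hap == 2L) hi else lo
    plants <- rbind(plants, data.frame(type = "ASM",
                                       chrom = cfg$chrom_name,
                                       start = st, end = en,
                                       hi_hap = hi_hap))
  }
  group_levels <- data.frame(region_id = integer(0),
                             sample = character(0), level = numeric(0))
  if (cfg$n_group_dmr > 0) {
    if (length(cfg$samples) < 2) {
      stop("group-DMR plants need at least two samples", call. = FALSE)
    }
    gpick <- pick[cfg$n_asm + seq_len(cfg$n_group_dmr)]
    for (j in seq_along(gpick)) {
      i <- gpick[j]
      st <- BiocGenerics::start(isl[i]); en <- BiocGenerics::end(isl[i])
      hi_s <- sample(seq_along(cfg$samples), 1)
      lv <- ifelse(seq_along(cfg$samples) == hi_s,
                   mean(hi_draw(200)), mean(lo_draw(200)))
      rid <- nrow(plants) + 1L
      plants <- rbind(plants, data.frame(type = "GROUP",
                                         chrom = cfg$chrom_name,
                                         start = st, end = en,
                                         hi_hap = NA_integer_))
      group_levels <- rbind(group_levels, data.frame(
        region_id = rid, sample = cfg$samples, level = lv))
    }
  }
  snv_plants <- data.frame(pos = integer(0), start = integer(0),
                           end = integer(0), p_carrier = numeric(0))
  if (cfg$n_snv_dmr > 0 && nrow(variants$snvs)) {
    used <- if (nrow(plants)) {
      IRanges::IRanges(plants$start, plants$end)
    } else IRanges::IRanges()
    cand <- variants$snvs$pos
    half <- 800L
    for (p in cand) {
      if (nrow(snv_plants) >= cfg$n_snv_dmr) break
      rg <- IRanges::IRanges(p - half, p + half)
      if (length(used) && any(IRanges::overlapsAny(rg, used))) next
      used <- c(used, rg)
      # carrier level: flip the local baseline by the configured diff
      in_r <- cpg$pos >= p - half & cpg$pos <= p + half
      base_mean <- mean(c(cpg$p_h1[in_r], cpg$p_h2[in_r]))
      p_car <- if (is.nan(base_mean) || base_mean < 0.5) {
        mean(hi_draw(200))
      } else mean(lo_draw(200))
      snv_plants <- rbind(snv_plants, data.frame(
        pos = p, start = p - half, end = p + half, p_carrier = p_car))
      plants <- rbind(plants, data.frame(type = "SNV",
                                         chrom = cfg$chrom_name,
                                         start = p - half, end = p + half,
                                         hi_hap = NA_integer_))
    }
  }
  if (nrow(plants) > 1L) {
    rg <- IRanges::IRanges(plants$start, plants$end)
    if (any(IRanges::countOverlaps(rg, rg) > 1L)) {
      stop("planted regions overlap", call. = FALSE)
    }
  }
  list(hap_genomes = hap_genomes, cpg = cpg, plants = plants,
       group_levels = group_levels, snv_plants = snv_plants)
}
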