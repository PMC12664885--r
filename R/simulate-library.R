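# P5/P7 grafting sequences retained outside the dual indexes in the
# multiplexed library design.
P5_FLANK <- "AATGATACGGCGACCACCGA"
P7_FLANK <- "CAAGCAGAAGACGGCATACGA"

.RAW_A <- charToRaw("A")[1]; .RAW_C <- charToRaw("C")[1]
.RAW_G <- charToRaw("G")[1]; .RAW_T <- charToRaw("T")[1]
.RAW_ACGT <- charToRaw("ACGT")

# substitution / insertion / deletion process over a raw sequence.
# Returns the errored sequence plus the CIGAR against the input
# coordinates and the shift of the alignment start caused by leading
# deletions.  Indels are kept away from the first/last template base so
# alignments never start or end in a gap.
.apply_errors <- function(seq_raw, sub_rate, ins_rate, del_rate,
                          want_cigar = FALSE) {
  L <- length(seq_raw)
  if (L == 0L) {
    return(list(seq = seq_raw, cigar = "", shift = 0L))
  }
  nsub <- rbinom(1L, L, sub_rate)
  if (nsub > 0L) {
    at <- sample.int(L, nsub)
    seq_raw[at] <- .RAW_ACGT[
      (match(as.integer(seq_raw[at]), as.integer(.RAW_ACGT)) - 1L +
         sample.int(3L, nsub, replace = TRUE)) %% 4L + 1L]
  }
  inner <- max(0L, L - 2L)
  ndel <- if (inner > 0L) rbinom(1L, inner, del_rate) else 0L
  nins <- if (inner > 0L) rbinom(1L, inner, ins_rate) else 0L
  if (ndel == 0L && nins == 0L) {
    return(list(seq = seq_raw,
                cigar = if (want_cigar) paste0(L, "M") else "",
                shift = 0L))
  }
  del_at <- if (ndel) 1L + sample.int(inner, ndel) else integer(0)
  ins_at <- if (nins) 1L + sample.int(inner, nins) else integer(0)
  keep <- rep(TRUE, L); keep[del_at] <- FALSE
  out <- seq_raw[keep]
  if (nins) {
    # insertion after template position p lands after the
    # corresponding kept position in the output
    ci <- cumsum(keep)
    at_out <- ci[ins_at]
    ord <- order(at_out)
    at_out <- at_out[ord]
    ins_b <- .RAW_ACGT[sample.int(4L, nins, replace = TRUE)][ord]
    res <- raw(length(out) + nins)
    tgt <- seq_along(out) + findInterval(seq_along(out) - 0.5, at_out)
    res[tgt] <- out
    res[at_out + seq_len(nins)] <- ins_b
    out <- res
  }
  cigar <- ""
  if (want_cigar) {
    ev <- rbind(
      if (ndel) cbind(pos = del_at, op = 2L) else NULL,
      if (nins) cbind(pos = ins_at + 0.5, op = 3L) else NULL
    )
    ev <- ev[order(ev[, "pos"]), , drop = FALSE]
    ops <- character(0); lens <- integer(0)
    cur <- 0
    push <- function(op, len) {
      if (len <= 0) return()
      if (length(ops) && ops[length(ops)] == op) {
        lens[length(lens)] <<- lens[length(lens)] + len
      } else {
        ops[length(ops) + 1L] <<- op
        lens[length(lens) + 1L] <<- len
      }
    }
    for (e in seq_len(nrow(ev))) {
      p <- ev[e, "pos"]; op <- ev[e, "op"]
      if (op == 2L) {          # deletion consumes template base p
        push("M", floor(p) - cur - 1L)
        push("D", 1L)
        cur <- floor(p)
      } else {                 # insertion after template base floor(p)
        push("M", floor(p) - cur)
        push("I", 1L)
        cur <- floor(p)
      }
    }
    push("M", L - cur)
    cigar <- paste0(lens, ops, collapse = "")
  }
  list(seq = out, cigar = cigar, shift = 0L)
}

#' Simulate a converted, capture-enriched sequencing library
#'
#' The generative model, molecule by molecule: draw a sample, a
#' haplotype (1/2 at random), a conversion frame (CT/GA at random — the
#' two strands of the original duplex), an on/off-target stratum, a
#' lognormal fragment; apply the haplotype's SNP alleles and, for
#' carrier molecules, somatic SNVs; draw every CpG's methylation state
#' from the molecule's probability vector (allele-, sample- and
#' carrier-aware, so methylation is molecule-coherent along the whole
#' fragment); convert unmethylated cytosines at the configured
#' efficiency (methylated ones escape protection at the over-conversion
#' rate); emit PCR duplicates sharing the converted template; and add
#' per-read substitution/indel sequencing errors.
#'
#' Truth alignments are recorded against the untransformed reference
#' with indel-consistent CIGARs and the conversion frame in the `XC`
#' tag, so downstream stages run without an aligner.  In multiplex mode
#' (a sample sheet in the config), reads additionally carry the retained
#' P5/P7 flanks with the sample's dual indexes, in random orientation,
#' with errors of their own.
#'
#' @param cfg A [sim_config()].
#' @param refobj,variants,methylome Upstream simulator stages.
#' @return list: `alignments` (truth `conv_alignments`), `reads` (truth
#'   table: read id, sample, molecule, duplicate_of, haplotype, space,
#'   fragment coordinates, SNV carrier status), `fastq` (data.frame
#'   `id`, `seq`, `qual` in sequencing orientation, flanked when
#'   multiplexed), `cpg_truth` (per-molecule CpG states, when
#'   `store_cpg_truth`), `carried_snvs` (molecule x SNV carrier table).
#' @export
simulate_library <- function(cfg, refobj, variants, methylome) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 3L)
  L <- as.integer(cfg$genome_length)
  mu <- log(cfg$fragment_n50) - cfg$fragment_sigma^2
  mean_len <- exp(mu + cfg$fragment_sigma^2 / 2)
  n_reads <- if (!is.null(cfg$n_reads)) as.integer(cfg$n_reads) else {
    as.integer(round(cfg$coverage * L / mean_len))
  }
  M <- max(1L, as.integer(round(n_reads * (1 - cfg$duplicate_rate))))
  mol_of_read <- c(seq_len(M),
                   if (n_reads > M) {
                     sample.int(M, n_reads - M, replace = TRUE)
                   } else integer(0))
  # --- per-molecule draws --------------------------------------------
  mol_sample <- sample(cfg$samples, M, replace = TRUE)
  mol_hap <- sample.int(2L, M, replace = TRUE)
  mol_space <- sample(c("CT", "GA"), M, replace = TRUE)
  mol_on <- runif(M) < cfg$p_on_target
  mol_len <- pmax(cfg$min_fragment,
                  round(rlnorm(M, mu, cfg$fragment_sigma)))
  mol_len <- pmin(mol_len, L - 1L)
  tg <- refobj$targets
  if (length(tg) == 0L) mol_on[] <- FALSE
  mol_start <- integer(M)
  if (any(mol_on)) {
    w <- as.numeric(width(tg))
    ti <- sample.int(length(tg), sum(mol_on), replace = TRUE,
                     prob = w / sum(w))
    mol_start[mol_on] <- BiocGenerics::start(tg)[ti] +
      floor(runif(sum(mol_on)) * w[ti])
  }
  mol_start[!mol_on] <- 1L + floor(runif(sum(!mol_on)) * (L - 1L))
  mol_start <- pmin(mol_start, pmax(1L, L - mol_len + 1L))
  mol_end <- pmin(L, mol_start + mol_len - 1L)
  # --- genome-indexed lookup tables ----------------------------------
  cpgdf <- methylome$cpg
  p_mat <- cbind(cpgdf$p_h1, cpgdf$p_h2)
  in_mat <- cbind(cpgdf$in_h1, cpgdf$in_h2)
  cpg_idx_of <- integer(L); cpg_idx_of[cpgdf$pos] <- seq_len(nrow(cpgdf))
  group_region <- integer(L)
  gl <- methylome$group_levels
  if (nrow(methylome$plants)) {
    gp <- which(methylome$plants$type == "GROUP")
    for (r in gp) {
      group_region[methylome$plants$start[r]:methylome$plants$end[r]] <- r
    }
  }
  snv_region <- integer(L)
  sp <- methylome$snv_plants
  if (nrow(sp)) for (r in seq_len(nrow(sp))) {
    snv_region[sp$start[r]:sp$end[r]] <- r
  }
  snvs <- variants$snvs
  hap_raw <- lapply(methylome$hap_genomes, charToRaw)
  eff <- cfg$conversion_efficiency
  over <- cfg$over_conversion_rate
  # --- molecule loop: conversion -------------------------------------
  mol_seq <- vector("list", M)
  cpg_truth <- vector("list", M)
  carried <- vector("list", M)
  for (m in seq_len(M)) {
    h <- mol_hap[m]; st <- mol_start[m]; en <- mol_end[m]
    frag <- hap_raw[[h]][st:en]
    # somatic SNVs carried by this molecule
    if (nrow(snvs)) {
      inw <- which(snvs$pos >= st & snvs$pos <= en & snvs$hap == h)
      if (length(inw)) {
        take <- inw[runif(length(inw)) < 2 * snvs$vaf[inw]]
        if (length(take)) {
          frag[snvs$pos[take] - st + 1L] <- charToRaw(
            paste(snvs$alt[take], collapse = ""))
          carried[[m]] <- snvs$pos[take]
        }
      }
    }
    if (mol_space[m] == "CT") {
      cidx <- which(frag == .RAW_C)
      gpos <- cidx + st - 1L               # genomic C positions
      ki <- cpg_idx_of[gpos]
      is_cpg <- ki > 0L & ifelse(ki > 0L, in_mat[pmax(ki, 1L), h], FALSE)
      vote_pos <- gpos[is_cpg]
    } else {
      gidx <- which(frag == .RAW_G)
      gpos <- gidx + st - 1L               # genomic G positions
      cpos <- gpos - 1L
      ki <- ifelse(cpos >= 1L, cpg_idx_of[pmax(cpos, 1L)], 0L)
      is_cpg <- ki > 0L & ifelse(ki > 0L, in_mat[pmax(ki, 1L), h], FALSE)
      vote_pos <- cpos[is_cpg]
      cidx <- gidx
    }
    n_cpg <- sum(is_cpg)
    if (n_cpg) {
      kk <- cpg_idx_of[vote_pos]
      p <- p_mat[kk, h]
      gr <- group_region[vote_pos]
      if (any(gr > 0L)) {
        lv <- gl$level[match(paste(gr[gr > 0L], mol_sample[m]),
                             paste(gl$region_id, gl$sample))]
        p[gr > 0L] <- lv
      }
      sr <- snv_region[vote_pos]
      if (any(sr > 0L) && length(carried[[m]])) {
        car_regions <- unique(snv_region[carried[[m]]])
        hit <- sr > 0L & sr %in% car_regions
        p[hit] <- sp$p_carrier[sr[hit]]
      }
      state <- runif(n_cpg) < p
      # methylated: protected unless over-converted;
      # unmethylated: converted unless conversion fails
      meth_keep <- state & (runif(n_cpg) >= over)
      unmeth_conv <- !state & (runif(n_cpg) < eff)
      convert <- logical(length(cidx))
      convert[is_cpg] <- (state & !meth_keep) | (!state & unmeth_conv)
      convert[!is_cpg] <- runif(sum(!is_cpg)) < eff
      frag[cidx[convert]] <- if (mol_space[m] == "CT") .RAW_T else .RAW_A
      if (cfg$store_cpg_truth) {
        cpg_truth[[m]] <- data.frame(molecule = m, pos = vote_pos,
                                     methylated = state)
      }
    } else {
      convert <- runif(length(cidx)) < eff
      frag[cidx[convert]] <- if (mol_space[m] == "CT") .RAW_T else .RAW_A
    }
    mol_seq[[m]] <- frag
  }
  # --- read emission with sequencing errors --------------------------
  n <- length(mol_of_read)
  read_id <- sprintf("read%06d", seq_len(n))
  seqs <- character(n); cigars <- character(n); pos <- integer(n)
  for (i in seq_len(n)) {
    m <- mol_of_read[i]
    er <- .apply_errors(mol_seq[[m]], cfg$sub_rate, cfg$ins_rate,
                        cfg$del_rate, want_cigar = TRUE)
    seqs[i] <- rawToChar(er$seq)
    cigars[i] <- if (nzchar(er$cigar)) er$cigar else {
      paste0(length(er$seq), "M")
    }
    pos[i] <- mol_start[m]
  }
  flags <- ifelse(mol_space[mol_of_read] == "GA", 16L, 0L)
  alignments <- conv_alignments(
    read_id = read_id, flag = flags, chrom = cfg$chrom_name,
    pos = pos, mapq = 60L, cigar = cigars, seq = seqs,
    space = mol_space[mol_of_read]
  )
  first_read <- match(seq_len(M), mol_of_read)
  dup_of <- ifelse(seq_len(n) == first_read[mol_of_read], NA_character_,
                   read_id[first_read[mol_of_read]])
  reads <- data.frame(
    read_id = read_id,
    sample = mol_sample[mol_of_read],
    molecule = mol_of_read,
    duplicate_of = dup_of,
    haplotype = mol_hap[mol_of_read],
    space = mol_space[mol_of_read],
    chrom = cfg$chrom_name,
    frag_start = mol_start[mol_of_read],
    frag_end = mol_end[mol_of_read],
    on_target = mol_on[mol_of_read],
    snv_carrier = lengths(carried)[mol_of_read] > 0L,
    stringsAsFactors = FALSE
  )
  # --- FASTQ ----------------------------------------------------------
  fq_seq <- seqs
  hopped <- rep(FALSE, n)
  if (!is.null(cfg$sheet)) {
    sheet <- cfg$sheet
    row <- match(reads$sample, sheet$sample_id)
    i7 <- sheet$i7[row]
    if (cfg$index_hop_rate > 0 && nrow(sheet) > 1L) {
      hopped <- runif(n) < cfg$index_hop_rate
      for (i in which(hopped)) {
        i7[i] <- sample(sheet$i7[-row[i]], 1)
      }
    }
    f5 <- paste0(P5_FLANK, sheet$i5[row])
    f3 <- paste0(revcomp(i7), revcomp(P7_FLANK))
    err_flank <- function(x) {
      vapply(x, function(s) {
        rawToChar(.apply_errors(charToRaw(s), cfg$sub_rate,
                                cfg$ins_rate, cfg$del_rate)$seq)
      }, character(1), USE.NAMES = FALSE)
    }
    fq_seq <- paste0(err_flank(f5), fq_seq, err_flank(f3))
  }
  flip <- runif(n) < 0.5
  fq_seq[flip] <- revcomp(fq_seq[flip])
  fastq <- data.frame(
    id = read_id, seq = fq_seq,
    qual = vapply(nchar(fq_seq), function(k) strrep("I", k),
                  character(1)),
    stringsAsFactors = FALSE
  )
  reads$hopped <- hopped
  carried_snvs <- if (any(lengths(carried) > 0)) {
    do.call(rbind, lapply(which(lengths(carried) > 0), function(m) {
      data.frame(molecule = m, snv_pos = carried[[m]])
    }))
  } else data.frame(molecule = integer(0), snv_pos = integer(0))
  list(
    alignments = alignments,
    reads = reads,
    fastq = fastq,
    cpg_truth = if (cfg$store_cpg_truth) {
      data.table::rbindlist(cpg_truth[!vapply(cpg_truth, is.null,
                                              logical(1))])
    } else NULL,
    carried_snvs = carried_snvs
  )
}

#' Truth phasing of the simulated het SNPs
#'
#' One truth block per chromosome with the simulated phase bits, in the
#' shape [phase_blocks()] produces, for switch-error evaluation.
#'
#' @param variants From [simulate_variants()].
#' @return A `phased_blocks` data.frame over the het SNPs.
#' @export
truth_phase <- function(variants) {
  snps <- variants$snps
  out <- data.frame(
    variant_idx = seq_len(nrow(snps)),
    block_id = as.integer(factor(snps$chrom)),
    hap1_is_alt = snps$hap1_is_alt
  )
  class(out) <- c("phased_blocks", "data.frame")
  out
}

#' Run the whole simulator and write its artifacts
#'
#' Convenience wrapper: reference, variants, methylome, library; writes
#' FASTA, targets/TSS BED, phased het-SNP VCF, somatic-SNV VCF, truth
#' SAM, FASTQ and the truth tables as TSV into `out_dir`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with all in-memory stage results plus
#'   `files` (named paths).
#' @export
simulate_experiment <- function(cfg, out_dir) {
  cfg <- validate_sim_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  refobj <- simulate_reference(cfg)
  variants <- simulate_variants(cfg, refobj)
  methylome <- simulate_methylome(cfg, refobj, variants)
  lib <- simulate_library(cfg, refobj, variants, methylome)
  files <- c(
    reference = file.path(out_dir, "reference.fa"),
    targets = file.path(out_dir, "targets.bed"),
    tss = file.path(out_dir, "tss.tsv"),
    het_vcf = file.path(out_dir, "het_snps.vcf"),
    snv_vcf = file.path(out_dir, "somatic_snvs.vcf"),
    truth_sam = file.path(out_dir, "truth.sam"),
    fastq = file.path(out_dir, "reads.fastq"),
    read_truth = file.path(out_dir, "read_truth.tsv"),
    methylome = file.path(out_dir, "methylome.tsv")
  )
  Biostrings::writeXStringSet(refobj$reference, files["reference"])
  write_bed(refobj$targets, files["targets"])
  utils::write.table(refobj$tss, files["tss"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_phased_vcf(variants$snps, files["het_vcf"], refobj$reference)
  write_snv_vcf(variants$snvs, files["snv_vcf"], refobj$reference)
  write_alignments_sam(lib$alignments, files["truth_sam"],
                       refobj$reference)
  write_fastq(lib$fastq$id, lib$fastq$seq, lib$fastq$qual,
              files["fastq"])
  utils::write.table(lib$reads, files["read_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(methylome$cpg, files["methylome"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(cfg = cfg, reference = refobj, variants = variants,
                 methylome = methylome, library = lib, files = files))
}
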