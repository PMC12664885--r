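# Independent oracles and small fixture builders shared across tests.

BASES <- c("A", "C", "G", "T")

# Brute-force allele-support oracle: enumerate convert_base over both
# alleles and both methylation states; compare the observation against
# the two reachable sets.  Kept deliberately independent of
# allele_support()'s set algebra.
oracle_support <- function(space, ref, alt, observed) {
  reach <- function(allele) {
    unique(c(convert_base(allele, space, methylated = TRUE),
             convert_base(allele, space, methylated = FALSE)))
  }
  if (observed == "N") return("OTHER")
  in_ref <- observed %in% reach(ref)
  in_alt <- observed %in% reach(alt)
  if (in_ref && in_alt) "AMBIGUOUS"
  else if (in_ref) "REF"
  else if (in_alt) "ALT"
  else "OTHER"
}

# Exhaustive minimum-error-correction phasing for tiny instances:
# tries all 2^(v-1) phasings and returns the orientation bits of the
# one minimising total read-allele mismatches.
oracle_mec_phase <- function(cells, n_var) {
  # cells: data.frame(read_id, variant_idx, value)
  best <- NULL; best_cost <- Inf
  for (mask in 0:(2^(n_var - 1) - 1)) {
    bits <- c(0L, as.integer(intToBits(mask))[seq_len(n_var - 1)])
    cost <- 0
    for (r in unique(cells$read_id)) {
      cc <- cells[cells$read_id == r, ]
      # read is from H1 or H2, whichever explains it best
      m1 <- sum(cc$value != bits[cc$variant_idx])
      m2 <- sum(cc$value != (1L - bits[cc$variant_idx]))
      cost <- cost + min(m1, m2)
    }
    if (cost < best_cost) { best_cost <- cost; best <- bits }
  }
  list(bits = best, cost = best_cost)
}

# Per-base brute-force capture metrics for tiny instances: walk every
# reference base of every alignment block and count.
oracle_hs_metrics <- function(alignments, targets, genome_size) {
  in_target <- function(chrom, p) {
    any(as.character(GenomicRanges::seqnames(targets)) == chrom &
          BiocGenerics::start(targets) <= p &
          BiocGenerics::end(targets) >= p)
  }
  use <- alignments[alignments$is_primary & !alignments$is_dup, ,
                    drop = FALSE]
  total <- 0; on <- 0; n_overlap <- 0
  for (i in seq_len(nrow(use))) {
    ops <- GenomicAlignments::explodeCigarOps(use$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(use$cigar[i])[[1]]
    p <- use$pos[i]
    touched <- FALSE
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X")) {
        for (q in p:(p + lens[k] - 1)) {
          total <- total + 1
          if (in_target(use$chrom[i], q)) on <- on + 1
        }
        p <- p + lens[k]
      } else if (ops[k] %in% c("D", "N")) {
        p <- p + lens[k]
      }
    }
    # overlap by >= 1 bp of the whole reference span
    span <- p - 1
    st <- use$pos[i]
    for (q in st:span) {
      if (in_target(use$chrom[i], q)) { touched <- TRUE; break }
    }
    if (touched) n_overlap <- n_overlap + 1
  }
  territory <- sum(BiocGenerics::width(targets))
  list(mean_bait_coverage = on / territory,
       fold_enrichment = if (total > 0) {
         (on / total) / (territory / genome_size)
       } else 0,
       on_target_read_rate = n_overlap / nrow(use))
}

# One-chromosome toy reference from an explicit sequence.
toy_reference <- function(seq, name = "toy") {
  Biostrings::DNAStringSet(stats::setNames(seq, name))
}

# Alignment container for reads given as (pos, seq) against a toy
# reference, all-M cigars unless given.
toy_alignments <- function(pos, seq, space = "CT", chrom = "toy",
                           cigar = NULL, flag = NULL, mapq = 60,
                           read_id = NULL) {
  n <- length(pos)
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(flag)) flag <- ifelse(rep_len(space, n) == "GA", 16L, 0L)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  conv_alignments(read_id = read_id, flag = flag, chrom = chrom,
                  pos = pos, mapq = mapq, cigar = cigar, seq = seq,
                  space = space)
}

# Default unique-dual-index sheet used by multiplex fixtures; pairwise
# edit distance (including reverse complements) is 4.
demo_sheet <- function() {
  read_sample_sheet(data.frame(
    sample_id = c("A", "B"),
    i5 = c("TATCCAGC", "GTACTCCT"),
    i7 = c("CCTCTATT", "CACTTCGA"),
    stringsAsFactors = FALSE
  ))
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

overlaps_plants <- function(pos, plants) {
  if (nrow(plants) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(plants))) {
    out <- out | (pos >= plants$start[k] & pos <= plants$end[k])
  }
  out
}
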