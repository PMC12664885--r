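# A deterministic toy setting: reference with variants at known
# positions, reads constructed by converting haplotype sequences.
toy_phasing_setup <- function() {
  #              1234567890123456789012345
  refseq <-     "AATTCAGGTTAACCAGTTAGACGTA"
  vars <- variant_table(
    chrom = "toy", pos = c(5, 10, 16, 21),
    ref = c("C", "T", "G", "A"), alt = c("A", "G", "T", "C"))
  list(ref = toy_reference(refseq), vars = vars)
}

# haplotype sequence for given alt mask over the 4 variants
.toy_hap <- function(setup, is_alt) {
  s <- as.character(setup$ref[[1]])
  v <- setup$vars
  for (k in seq_len(nrow(v))) {
    b <- if (is_alt[k]) v$alt[k] else v$ref[k]
    substr(s, v$pos[k], v$pos[k]) <- b
  }
  s
}

.convert_seq <- function(s, space) {
  paste(convert_base(strsplit(s, "")[[1]], space, FALSE), collapse = "")
}

test_that("allele matrix scores conversion-aware support per cell", {
  st <- toy_phasing_setup()
  # CT-space read observing A at the C>A site supports ALT
  h <- .toy_hap(st, c(TRUE, FALSE, FALSE, FALSE))
  aln <- toy_alignments(1, .convert_seq(h, "CT"), space = "CT")
  m <- build_allele_matrix(aln, st$vars, st$ref)
  expect_identical(m$support[m$variant_idx == 1], "ALT")
  # site 2 is T>G: CT conversion leaves both alleles literal
  expect_identical(m$support[m$variant_idx == 2], "REF")
  # supplementary alignments contribute no cells
  supp <- toy_alignments(1, .convert_seq(h, "CT"), space = "CT",
                         flag = 2048L)
  expect_identical(nrow(build_allele_matrix(supp, st$vars, st$ref)), 0L)
  # reads not overlapping any variant contribute no cells
  far <- toy_alignments(23, "GTA", space = "CT")
  expect_identical(nrow(build_allele_matrix(far, st$vars, st$ref)), 0L)
  expect_error(
    build_allele_matrix(aln, variant_table("toy", 999, "A", "C"),
                        st$ref),
    "bounds")
})

test_that("ambiguous observations stay inert in the matrix", {
  # C>T site read as T in CT space cannot be resolved
  vars <- variant_table("toy", 5, "C", "T")
  st <- toy_phasing_setup()
  aln <- toy_alignments(1, .convert_seq(as.character(st$ref[[1]]), "CT"),
                        space = "CT")
  m <- build_allele_matrix(aln, vars, st$ref)
  expect_identical(m$support, "AMBIGUOUS")
  # but the GA frame resolves it
  aln_ga <- toy_alignments(1, .convert_seq(as.character(st$ref[[1]]),
                                           "GA"), space = "GA")
  m_ga <- build_allele_matrix(aln_ga, vars, st$ref)
  expect_identical(m_ga$support, "REF")
})

test_that("pseudo reads carry restored bases and N elsewhere", {
  st <- toy_phasing_setup()
  h <- .toy_hap(st, c(TRUE, TRUE, FALSE, FALSE))
  aln <- toy_alignments(1, .convert_seq(h, "CT"), space = "CT")
  m <- build_allele_matrix(aln, st$vars, st$ref)
  ps <- make_pseudo_reads(m, aln, st$vars)
  expect_identical(nrow(ps), 1L)
  s <- strsplit(ps$seq, "")[[1]]
  expect_identical(s[st$vars$pos], c("A", "G", "G", "A"))
  expect_true(all(s[-st$vars$pos] == "N"))
  # a read with only ambiguous cells yields no pseudo read: the
  # reference C at a C>T site converts to T, reachable from both
  vars_amb <- variant_table("toy", 5, "C", "T")
  aln <- toy_alignments(1, .convert_seq(as.character(st$ref[[1]]),
                                        "CT"), space = "CT")
  m2 <- build_allele_matrix(aln, vars_amb, st$ref)
  expect_identical(m2$support, "AMBIGUOUS")
  expect_identical(nrow(make_pseudo_reads(m2, aln, vars_amb)), 0L)
})

test_that("pseudo-read SAM export round-trips exactly", {
  st <- toy_phasing_setup()
  h1 <- .toy_hap(st, c(TRUE, FALSE, TRUE, FALSE))
  h2 <- .toy_hap(st, c(FALSE, TRUE, FALSE, TRUE))
  aln <- toy_alignments(c(1, 1), c(.convert_seq(h1, "CT"),
                                   .convert_seq(h2, "GA")),
                        space = c("CT", "GA"))
  m <- build_allele_matrix(aln, st$vars, st$ref)
  ps <- make_pseudo_reads(m, aln, st$vars)
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(ps, sam, st$ref)
  back <- read_alignments(sam)
  for (cl in c("read_id", "pos", "cigar", "seq", "space")) {
    expect_identical(back[[cl]], ps[[cl]], info = cl)
  }
})

test_that("phase_blocks reconstructs truth and splits unlinked sites", {
  st <- toy_phasing_setup()
  truth_bits <- c(1L, 0L, 1L, 0L)
  set.seed(31)
  # 20 error-free reads spanning adjacent variant pairs
  spans <- list(c(1, 12), c(7, 18), c(13, 25))
  seqs <- character(0); pos <- integer(0); spaces <- character(0)
  for (i in 1:20) {
    sp <- spans[[(i %% 3) + 1]]
    hap <- (i %% 2) + 1
    is_alt <- if (hap == 1) truth_bits == 1L else truth_bits == 0L
    h <- .toy_hap(st, is_alt)
    space <- sample(c("CT", "GA"), 1)
    seqs <- c(seqs, .convert_seq(substring(h, sp[1], sp[2]), space))
    pos <- c(pos, sp[1]); spaces <- c(spaces, space)
  }
  aln <- toy_alignments(pos, seqs, space = spaces)
  m <- build_allele_matrix(aln, st$vars, st$ref)
  blocks <- phase_blocks(m, st$vars)
  expect_identical(length(unique(blocks$block_id)), 1L)
  expect_identical(nrow(blocks), 4L)
  # phase matches truth up to a global flip
  agree <- blocks$hap1_is_alt == truth_bits[blocks$variant_idx]
  expect_true(all(agree) || all(!agree))
  # switch error against truth is zero
  tr <- data.frame(variant_idx = 1:4, block_id = 1L,
                   hap1_is_alt = truth_bits)
  se <- switch_error_rate(blocks, tr, st$vars)
  expect_identical(se$switch_error_rate, 0)
  expect_identical(se$n_comparable_pairs, 3L)
})

test_that("unlinked variant clusters become separate blocks", {
  st <- toy_phasing_setup()
  h <- .toy_hap(st, c(TRUE, TRUE, TRUE, TRUE))
  # reads only span variants {1,2} or {3,4}: two blocks
  aln <- toy_alignments(
    pos = c(1, 1, 1, 13, 13, 13),
    seq = c(rep(.convert_seq(substring(h, 1, 12), "CT"), 3),
            rep(.convert_seq(substring(h, 13, 25), "CT"), 3)),
    space = "CT")
  m <- build_allele_matrix(aln, st$vars, st$ref)
  blocks <- phase_blocks(m, st$vars)
  expect_identical(length(unique(blocks$block_id)), 2L)
  # cis == trans ties drop the edge entirely
  h_a <- .toy_hap(st, c(TRUE, TRUE, FALSE, FALSE))
  h_b <- .toy_hap(st, c(TRUE, FALSE, FALSE, FALSE))
  tie <- toy_alignments(
    pos = c(1, 1, 1, 1),
    seq = c(rep(.convert_seq(substring(h_a, 1, 12), "CT"), 2),
            rep(.convert_seq(substring(h_b, 1, 12), "CT"), 2)),
    space = "CT")
  m_tie <- build_allele_matrix(tie, st$vars, st$ref)
  expect_identical(nrow(phase_blocks(m_tie, st$vars)), 0L)
})

test_that("spanning-forest phasing is MEC-optimal on small instances", {
  set.seed(41)
  for (trial in 1:8) {
    n_var <- sample(4:7, 1)
    n_reads <- sample(8:16, 1)
    truth <- rbinom(n_var, 1, 0.5)
    cells <- do.call(rbind, lapply(seq_len(n_reads), function(r) {
      a <- sort(sample.int(n_var, sample(2:min(4, n_var), 1)))
      hap <- sample(1:2, 1)
      val <- if (hap == 1) truth[a] else 1L - truth[a]
      data.frame(read_id = sprintf("r%02d", r), variant_idx = a,
                 value = val)
    }))
    # error-free instance: the internal phaser must reach the MEC
    # optimum (cost 0) with the same relative orientations
    mx <- data.frame(read_id = cells$read_id, aln_idx = NA_integer_,
                     variant_idx = cells$variant_idx,
                     observed = "A",
                     support = ifelse(cells$value == 1, "ALT", "REF"))
    class(mx) <- c("allele_matrix", "data.frame")
    vars <- variant_table("toy", seq_len(n_var) * 10, "A", "C")
    blocks <- phase_blocks(mx, vars, min_link = 1)
    mec <- oracle_mec_phase(cells, n_var)
    expect_identical(mec$cost, 0)
    for (b in unique(blocks$block_id)) {
      i <- blocks$block_id == b
      agree <- blocks$hap1_is_alt[i] ==
        mec$bits[blocks$variant_idx[i]]
      expect_true(all(agree) || all(!agree))
    }
  }
})

test_that("haplotagging follows the majority-with-margin rule", {
  st <- toy_phasing_setup()
  blocks <- data.frame(variant_idx = 1:4, block_id = 1L,
                       hap1_is_alt = c(1L, 0L, 1L, 0L))
  mk_matrix <- function(support) {
    mx <- data.frame(read_id = "r1", aln_idx = 1L,
                     variant_idx = seq_along(support),
                     observed = "A", support = support)
    class(mx) <- c("allele_matrix", "data.frame")
    mx
  }
  # matches H1 at 3/3 phased sites
  tags <- haplotag_reads(mk_matrix(c("ALT", "REF", "ALT")), blocks,
                         st$vars)
  expect_identical(tags$haplotype, "H1")
  expect_identical(tags$n_informative, 3L)
  # 2-2 split is a tie: values (1,0,0,1) against bits (1,0,1,0)
  tags2 <- haplotag_reads(mk_matrix(c("ALT", "REF", "REF", "ALT")),
                          blocks, st$vars)
  expect_identical(tags2$haplotype, "UNTAGGED")
  # a min_sites floor suppresses thin evidence
  tags3 <- haplotag_reads(mk_matrix("ALT"), blocks, st$vars,
                          min_sites = 2)
  expect_identical(tags3$haplotype, "UNTAGGED")
})

test_that("unphased-SNP mode records per-site allele groups", {
  vars <- variant_table("toy", c(5, 50), c("C", "T"), c("A", "G"))
  mx <- data.frame(read_id = c("r1", "r2"), aln_idx = 1:2,
                   variant_idx = c(2L, 2L), observed = c("G", "T"),
                   support = c("ALT", "REF"))
  class(mx) <- c("allele_matrix", "data.frame")
  blocks <- data.frame(variant_idx = integer(0), block_id = integer(0),
                       hap1_is_alt = integer(0))
  tags <- haplotag_reads(mx, blocks, vars, mode = "WITH_UNPHASED_SNPS")
  sg <- attr(tags, "site_groups")
  expect_identical(nrow(sg), 2L)
  expect_setequal(sg$allele, c("ALT", "REF"))
  expect_true(all(tags$haplotype == "UNTAGGED"))
})

test_that("SNV classification separates carrier from reference reads", {
  vars <- variant_table("toy", c(5, 50), c("C", "T"), c("A", "G"),
                        kind = "SOMATIC_SNV")
  mk <- function(read_id, variant_idx, support) {
    mx <- data.frame(read_id = read_id, aln_idx = seq_along(read_id),
                     variant_idx = variant_idx, observed = "A",
                     support = support)
    class(mx) <- c("allele_matrix", "data.frame")
    mx
  }
  # ALT at one of two covered SNVs
  cls <- classify_by_snv(mk(rep("r1", 2), c(1L, 2L), c("ALT", "REF")),
                         vars)
  expect_identical(cls$class, "SNV_PLUS")
  # REF at the single covered SNV
  cls2 <- classify_by_snv(mk("r2", 1L, "REF"), vars)
  expect_identical(cls2$class, "SNV_MINUS")
  # only ambiguous coverage
  cls3 <- classify_by_snv(mk("r3", 1L, "AMBIGUOUS"), vars)
  expect_identical(cls3$class, "UNASSIGNED")
})

test_that("switch errors count flipped suffixes but not global flips", {
  vars <- variant_table("toy", c(10, 20, 30, 40), "A", "C")
  base <- data.frame(variant_idx = 1:4, block_id = 1L,
                     hap1_is_alt = c(0L, 1L, 0L, 1L))
  expect_identical(switch_error_rate(base, base,
                                     vars)$switch_error_rate, 0)
  # flipped suffix of 2 variants: one switch over three pairs
  suffix <- base
  suffix$hap1_is_alt[3:4] <- 1L - suffix$hap1_is_alt[3:4]
  se <- switch_error_rate(suffix, base, vars)
  expect_equal(se$switch_error_rate, 1 / 3)
  expect_identical(se$n_switches, 1L)
  # globally flipped block: phase is relative, no switches
  flip <- base
  flip$hap1_is_alt <- 1L - flip$hap1_is_alt
  expect_identical(switch_error_rate(flip, base,
                                     vars)$switch_error_rate, 0)
  # disjoint phasings have no comparable pairs
  none <- data.frame(variant_idx = integer(0), block_id = integer(0),
                     hap1_is_alt = integer(0))
  se0 <- switch_error_rate(none, base, vars)
  expect_true(is.na(se0$switch_error_rate))
  expect_identical(se0$n_comparable_pairs, 0L)
})

test_that("flip invariance holds for random block subsets", {
  set.seed(51)
  vars <- variant_table("toy", seq(10, 200, by = 10), "A", "C")
  test <- data.frame(variant_idx = 1:20,
                     block_id = rep(1:4, each = 5),
                     hap1_is_alt = rbinom(20, 1, 0.5))
  truth <- data.frame(variant_idx = 1:20, block_id = 1L,
                      hap1_is_alt = rbinom(20, 1, 0.5))
  base_rate <- switch_error_rate(test, truth, vars)$switch_error_rate
  for (b in 1:4) {
    flipped <- test
    i <- flipped$block_id == b
    flipped$hap1_is_alt[i] <- 1L - flipped$hap1_is_alt[i]
    expect_equal(switch_error_rate(flipped, truth,
                                   vars)$switch_error_rate, base_rate)
  }
})
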