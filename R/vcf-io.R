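.vcf_header <- function(reference, extra = character(0)) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(reference), ",length=",
           width(reference), ">"),
    extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "SAMPLE"), collapse = "\t"))
}

#' Write phased heterozygous SNPs as VCF
#'
#' Emits phased genotypes (`1|0` when haplotype 1 carries the alternate,
#' `0|1` otherwise) with a `PS` phase-set tag.  One phase set per
#' chromosome unless a `block_id` column is present.
#'
#' @param snps data.frame `chrom`, `pos`, `ref`, `alt`, `hap1_is_alt`,
#'   optionally `block_id`.
#' @param file Output path.
#' @param reference [Biostrings::DNAStringSet] for the contig header.
#' @return The path, invisibly.
#' @export
write_phased_vcf <- function(snps, file, reference) {
  ps <- if ("block_id" %in% names(snps)) snps$block_id else {
    as.integer(factor(snps$chrom))
  }
  gt <- ifelse(snps$hap1_is_alt == 1L, "1|0", "0|1")
  rec <- paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".",
               "PASS", ".", "GT:PS", paste0(gt, ":", ps), sep = "\t")
  writeLines(c(.vcf_header(
    reference,
    c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">")
  ), rec), file)
  invisible(file)
}

#' Write somatic SNVs as VCF
#'
#' Unphased heterozygous genotypes with the variant allele fraction in
#' the `AF` info field.
#'
#' @param snvs data.frame `chrom`, `pos`, `ref`, `alt`, `vaf`.
#' @param file Output path.
#' @param reference [Biostrings::DNAStringSet] for the contig header.
#' @return The path, invisibly.
#' @export
write_snv_vcf <- function(snvs, file, reference) {
  rec <- if (nrow(snvs)) {
    paste(snvs$chrom, snvs$pos, ".", snvs$ref, snvs$alt, ".", "PASS",
          paste0("AF=", snvs$vaf), "GT", "0/1", sep = "\t")
  } else character(0)
  writeLines(c(.vcf_header(
    reference,
    c("##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  ), rec), file)
  invisible(file)
}

#' Read biallelic SNVs from a VCF
#'
#' Loads a VCF via `vcfR`, keeps biallelic SNVs, and returns a
#' [variant_table()].  For phased VCFs (pipe-separated genotypes) the
#' phase bits and phase sets are attached as a `phased_blocks` attribute,
#' so an external phaser's output can drive [haplotag_reads()].
#'
#' @param file VCF path.
#' @param kind `"HET_SNP"` or `"SOMATIC_SNV"` label for the rows.
#' @return A [variant_table()]; attribute `"phase"` holds a
#'   `phased_blocks` data.frame when phased genotypes are present.
#' @export
read_variants_vcf <- function(file, kind = "HET_SNP") {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  fix <- fix[keep, , drop = FALSE]
  vt <- variant_table(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT,
                      kind = kind)
  if (nrow(v@gt) && any(keep)) {
    gt <- vcfR::extract.gt(v, element = "GT")[keep, 1]
    ps <- tryCatch(vcfR::extract.gt(v, element = "PS")[keep, 1],
                   error = function(e) rep(NA_character_, sum(keep)))
    # rows of vt are sorted; map back
    ord <- order(fix$CHROM, as.integer(fix$POS))
    gt <- gt[ord]; ps <- ps[ord]
    phased <- grepl("^[01]\\|[01]$", gt)
    if (any(phased)) {
      hap1 <- as.integer(substring(gt[phased], 1, 1))
      block <- ps[phased]
      block[is.na(block)] <- paste0("chr:", vt$chrom[phased][is.na(block)])
      ph <- data.frame(variant_idx = which(phased),
                       block_id = as.integer(factor(block)),
                       hap1_is_alt = hap1)
      class(ph) <- c("phased_blocks", "data.frame")
      attr(vt, "phase") <- ph
    }
  }
  vt
}
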