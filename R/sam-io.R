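#' Construct a container of aligned converted reads
#'
#' `conv_alignments` is the unit all downstream operations consume: a
#' data.frame with one row per SAM record, holding the query name, flag,
#' chromosome, 1-based leftmost position, MAPQ, CIGAR, query sequence and
#' the conversion space (`CT`/`GA`/`UNKNOWN`).  Coordinates are 1-based
#' inclusive internally (the R/Bioconductor convention); BED and bedGraph
#' writers convert at the boundary.
#'
#' @param read_id,flag,chrom,pos,mapq,cigar,seq,space Per-record vectors.
#' @return A `conv_alignments` data.frame with derived columns
#'   `is_primary`, `strand` and `is_dup` (initially `FALSE`).
#' @export
conv_alignments <- function(read_id, flag, chrom, pos, mapq, cigar, seq,
                            space = "UNKNOWN") {
  df <- data.frame(
    read_id = as.character(read_id),
    flag = as.integer(flag),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    mapq = as.integer(mapq),
    cigar = as.character(cigar),
    seq = as.character(seq),
    space = rep_len(as.character(space), length(read_id)),
    stringsAsFactors = FALSE
  )
  df$is_primary <- bitwAnd(df$flag, 0x900L) == 0L
  df$strand <- ifelse(bitwAnd(df$flag, 0x10L) > 0L, "-", "+")
  df$is_dup <- bitwAnd(df$flag, 0x400L) > 0L
  class(df) <- c("conv_alignments", "data.frame")
  df
}

#' Read converted-read alignments from SAM/BAM
#'
#' Parses a SAM (or BAM) file via Rsamtools and returns a
#' [conv_alignments()] container.  When the records carry a
#' conversion-space tag (default `XC`, values `"CT"`/`"GA"`) it is trusted;
#' otherwise the space is `UNKNOWN` and can be filled in with
#' [classify_read_space()].
#'
#' @param file Path to a SAM or BAM file.
#' @param space_tag Two-letter tag naming the conversion space
#'   (default `"XC"`); set `NULL` to skip tag lookup.
#' @return A `conv_alignments` data.frame (unmapped records dropped).
#' @export
read_alignments <- function(file, space_tag = "XC") {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  param <- Rsamtools::ScanBamParam(
    what = what,
    tag = if (is.null(space_tag)) character(0) else space_tag
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$pos)
  space <- rep("UNKNOWN", length(res$qname))
  if (!is.null(space_tag) && !is.null(res$tag[[space_tag]])) {
    tg <- res$tag[[space_tag]]
    space[!is.na(tg) & tg %in% c("CT", "GA")] <-
      tg[!is.na(tg) & tg %in% c("CT", "GA")]
  }
  conv_alignments(
    read_id = res$qname[keep],
    flag = res$flag[keep],
    chrom = as.character(res$rname)[keep],
    pos = res$pos[keep],
    mapq = res$mapq[keep],
    cigar = res$cigar[keep],
    seq = as.character(res$seq)[keep],
    space = space[keep]
  )
}

#' Write alignments as SAM text
#'
#' Emits a coordinate-sorted SAM file with an `@SQ` header derived from the
#' reference and the conversion space stored in a tag.  Used for the
#' simulator's truth alignments and for pseudo-read export.
#'
#' @param alignments A `conv_alignments` object.
#' @param file Output path.
#' @param reference [Biostrings::DNAStringSet] supplying sequence names and
#'   lengths for the header.
#' @param space_tag Tag used for the conversion space (default `"XC"`).
#' @return The path, invisibly.
#' @export
write_alignments_sam <- function(alignments, file, reference,
                                 space_tag = "XC") {
  stopifnot(inherits(alignments, "conv_alignments"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(reference), "\tLN:", width(reference)))
  ord <- order(alignments$chrom, alignments$pos)
  a <- alignments[ord, , drop = FALSE]
  flag <- a$flag
  flag <- ifelse(a$is_dup, bitwOr(flag, 0x400L), flag)
  tagf <- ifelse(a$space %in% c("CT", "GA"),
                 paste0("\t", space_tag, ":Z:", a$space), "")
  rec <- paste0(a$read_id, "\t", flag, "\t", a$chrom, "\t", a$pos,
                "\t", a$mapq, "\t", a$cigar, "\t*\t0\t0\t", a$seq,
                "\t*", tagf)
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rec), con)
  invisible(file)
}

# width helper without attaching Biostrings generics in user code
width <- function(x) Biostrings::width(x)

#' Project query sequences into reference space
#'
#' Uses the CIGAR to lay each query sequence along the reference: deletions
#' become `-`, insertions are removed.  The result for row `i` has exactly
#' `cigarWidthAlongReferenceSpace(cigar[i])` characters starting at
#' `pos[i]`.
#'
#' @param alignments A `conv_alignments` object.
#' @return Character vector of reference-space sequences.
#' @export
project_to_reference <- function(alignments) {
  stopifnot(inherits(alignments, "conv_alignments"))
  if (nrow(alignments) == 0L) return(character(0))
  laid <- GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(alignments$seq), alignments$cigar,
    from = "query", to = "reference"
  )
  as.character(laid)
}

# Extract reference windows (chrom, start, width) as character strings.
reference_window <- function(reference, chrom, start, width_) {
  width_ <- rep_len(width_, length(chrom))
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    refstr <- as.character(reference[[ch]])
    out[i] <- substring(refstr, start[i], start[i] + width_[i] - 1L)
  }
  out
}

#' Reference span width of each alignment
#' @param alignments A `conv_alignments` object.
#' @return Integer vector of reference-consumed widths.
#' @export
reference_width <- function(alignments) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(alignments$cigar)
}

#' Alignments as a GRanges of reference spans
#' @param alignments A `conv_alignments` object.
#' @return A [GenomicRanges::GRanges] (one range per record).
#' @export
alignment_ranges <- function(alignments) {
  GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$pos,
                     width = reference_width(alignments)),
    strand = alignments$strand
  )
}

#' Extract read bases over given genomic positions
#'
#' For every (alignment, position) pair where the alignment's reference
#' span covers the position, reports the read base laid over it (`-` for a
#' deletion).  This is the pileup primitive behind allele-matrix
#' construction and CpG methylation calling.
#'
#' @param alignments A `conv_alignments` object.
#' @param sites data.frame with columns `chrom` and `pos` (1-based).
#' @return data.frame with `aln_idx`, `site_idx`, `base`.
#' @export
extract_bases_at <- function(alignments, sites) {
  stopifnot(inherits(alignments, "conv_alignments"))
  if (nrow(alignments) == 0L || nrow(sites) == 0L) {
    return(data.frame(aln_idx = integer(0), site_idx = integer(0),
                      base = character(0), stringsAsFactors = FALSE))
  }
  rg <- alignment_ranges(alignments)
  sg <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(sg, rg, ignore.strand = TRUE)
  if (length(ov) == 0L) {
    return(data.frame(aln_idx = integer(0), site_idx = integer(0),
                      base = character(0), stringsAsFactors = FALSE))
  }
  si <- S4Vectors::queryHits(ov)
  ai <- S4Vectors::subjectHits(ov)
  proj <- project_to_reference(alignments)
  off <- sites$pos[si] - alignments$pos[ai] + 1L
  base <- substring(proj[ai], off, off)
  data.frame(aln_idx = ai, site_idx = si, base = base,
             stringsAsFactors = FALSE)
}

#' Find CpG sites in a reference
#'
#' Positions of the `C` of every top-strand `CG` dinucleotide.
#'
#' @param reference A [Biostrings::DNAStringSet].
#' @return data.frame with `chrom`, `pos` (1-based position of the C).
#' @export
find_cpg_sites <- function(reference) {
  out <- lapply(names(reference), function(ch) {
    m <- Biostrings::matchPattern("CG", reference[[ch]])
    data.frame(chrom = ch, pos = BiocGenerics::start(m))
  })
  do.call(rbind, out)
}

#' Read a reference FASTA
#' @param file FASTA path.
#' @return A [Biostrings::DNAStringSet] with names stripped of comments.
#' @export
read_reference <- function(file) {
  ref <- Biostrings::readDNAStringSet(file)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
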