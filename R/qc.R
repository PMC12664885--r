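#' Load a capture target BED into merged intervals
#'
#' @param file BED path (0-based half-open) or a
#'   [GenomicRanges::GRanges].
#' @return A merged, disjoint, unstranded `GRanges` with metadata
#'   attribute dropped; territory is `sum(width())`.
#' @export
read_targets <- function(file) {
  gr <- if (methods::is(file, "GRanges")) file else {
    df <- utils::read.table(file, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    GenomicRanges::GRanges(df[[1]],
                           IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::granges(gr),
                              ignore.strand = TRUE)
  if (sum(width(gr)) <= 0) stop("target territory is empty",
                                call. = FALSE)
  gr
}

#' Write intervals as BED (0-based half-open)
#' @param gr A `GRanges`. @param file Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(gr, file) {
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# unclipped 5' start of each alignment (the position the duplicate key
# uses): leading soft/hard clips extend the start on +, trailing clips
# extend the end on -.
.unclipped_five_prime <- function(alignments) {
  cig <- alignments$cigar
  lead <- trail <- integer(length(cig))
  has_lead <- grepl("^\\d+[SH]", cig)
  lead[has_lead] <- as.integer(sub("^(\\d+)[SH].*$", "\\1",
                                   cig[has_lead]))
  has_trail <- grepl("\\d+[SH]$", cig)
  trail[has_trail] <- as.integer(sub("^.*?(\\d+)[SH]$", "\\1",
                                     cig[has_trail]))
  w <- reference_width(alignments)
  ifelse(alignments$strand == "+",
         alignments$pos - lead,
         alignments$pos + w - 1L + trail)
}

#' Mark PCR/optical duplicates among long-read alignments
#'
#' Single-end duplicate marking: records sharing (chromosome,
#' orientation, unclipped 5' start) — optionally also a 3' end within
#' `end_tolerance` — are one duplicate set; the representative is the
#' record with the longest aligned span (ties broken by lexicographic
#' read id), the rest are flagged.  Requires coordinate-sorted primary
#' alignments; secondary/supplementary records are never flagged and do
#' not participate.
#'
#' @param alignments A `conv_alignments` object, coordinate-sorted.
#' @param use_end Also require matching 3' end (default FALSE).
#' @param end_tolerance Tolerance in bp for the 3' end when `use_end`
#'   (default 0).
#' @return The alignments with `is_dup` set; attribute
#'   `"duplicate_rate"` = flagged / primary records.
#' @export
mark_duplicates <- function(alignments, use_end = FALSE,
                            end_tolerance = 0) {
  stopifnot(inherits(alignments, "conv_alignments"))
  prim <- which(alignments$is_primary)
  if (length(prim)) {
    p <- alignments[prim, , drop = FALSE]
    if (any(tapply(p$pos, p$chrom, is.unsorted))) {
      stop("alignments must be coordinate-sorted", call. = FALSE)
    }
    u5 <- .unclipped_five_prime(p)
    key <- paste(p$chrom, p$strand, u5)
    if (use_end) {
      u3 <- ifelse(p$strand == "+", p$pos + reference_width(p) - 1L,
                   p$pos)
      bin <- if (end_tolerance > 0) {
        round(u3 / max(1, end_tolerance))
      } else u3
      key <- paste(key, bin)
    }
    span <- reference_width(p)
    ord <- order(key, -span, p$read_id)
    dup <- duplicated(key[ord])
    is_dup <- logical(nrow(p))
    is_dup[ord] <- dup
    alignments$is_dup[prim] <- is_dup
    alignments$flag[prim] <- ifelse(is_dup,
                                    bitwOr(alignments$flag[prim], 0x400L),
                                    bitwAnd(alignments$flag[prim],
                                            bitwNot(0x400L)))
    attr(alignments, "duplicate_rate") <- mean(is_dup)
  } else {
    attr(alignments, "duplicate_rate") <- NA_real_
  }
  alignments
}

# reference ranges of alignment-consuming (M/=/X) bases per record
.aligned_block_ranges <- function(alignments) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alignments$cigar, pos = alignments$pos,
    ops = c("M", "=", "X")
  )
  n <- S4Vectors::elementNROWS(rl)
  GenomicRanges::GRanges(rep(alignments$chrom, n), unlist(rl))
}

#' Hybridization-capture metrics
#'
#' Over non-duplicate primary alignments: `mean_bait_coverage` =
#' on-target aligned bases / target territory; `fold_enrichment` =
#' (on-target aligned bases / total aligned bases) / (territory /
#' genome size); plus on-target read rate, duplicate rate (of primary
#' records), and read N50 over query lengths.  Aligned bases are the
#' reference-consuming matched bases (CIGAR `M`/`=`/`X`); clips never
#' count.
#'
#' @param alignments A `conv_alignments` object (run
#'   [mark_duplicates()] first if duplicates should be excluded).
#' @param targets A merged target `GRanges` from [read_targets()].
#' @param genome_size Total genome length in bp.
#' @return An `hs_metrics` list.
#' @export
hs_metrics <- function(alignments, targets, genome_size) {
  territory <- sum(width(targets))
  stopifnot(genome_size >= territory, territory > 0)
  prim <- alignments[alignments$is_primary, , drop = FALSE]
  use <- prim[!prim$is_dup, , drop = FALSE]
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    use$cigar, after.soft.clipping = FALSE)
  if (nrow(use) == 0L) {
    warning("no aligned bases; metrics reported as 0")
    return(structure(list(mean_bait_coverage = 0, fold_enrichment = 0,
                          on_target_read_rate = 0,
                          duplicate_rate = attr(alignments,
                                                "duplicate_rate") %||% 0,
                          read_n50 = 0, total_aligned_bases = 0,
                          on_target_bases = 0, territory = territory),
                     class = "hs_metrics"))
  }
  blocks <- .aligned_block_ranges(use)
  total_bases <- sum(as.numeric(width(blocks)))
  # on-target bases are counted per read (coverage-style, so stacked
  # reads each contribute), against the merged target set
  ov <- GenomicRanges::findOverlaps(blocks, targets, ignore.strand = TRUE)
  pint <- GenomicRanges::pintersect(
    blocks[S4Vectors::queryHits(ov)],
    targets[S4Vectors::subjectHits(ov)], ignore.strand = TRUE)
  on_bases <- sum(as.numeric(width(pint)))
  structure(list(
    mean_bait_coverage = on_bases / territory,
    fold_enrichment = (on_bases / total_bases) /
      (territory / genome_size),
    on_target_read_rate = overlap_rate(alignments, targets),
    duplicate_rate = attr(alignments, "duplicate_rate") %||%
      mean(prim$is_dup),
    read_n50 = n50(qlen),
    total_aligned_bases = total_bases,
    on_target_bases = on_bases,
    territory = territory
  ), class = "hs_metrics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of reads overlapping the targets
#'
#' Mapped, non-duplicate primary reads whose reference span overlaps any
#' target by at least one base, over all such reads.
#'
#' @param alignments A `conv_alignments` object.
#' @param targets Target `GRanges`.
#' @param include_duplicates Count flagged duplicates too (default
#'   FALSE).
#' @return A fraction in `[0, 1]`.
#' @export
overlap_rate <- function(alignments, targets,
                         include_duplicates = FALSE) {
  use <- alignments[alignments$is_primary &
                      (include_duplicates | !alignments$is_dup), ,
                    drop = FALSE]
  if (nrow(use) == 0L) return(NA_real_)
  rg <- alignment_ranges(use)
  mean(IRanges::overlapsAny(rg, targets, minoverlap = 1L,
                            ignore.strand = TRUE))
}

#' Per-CpG read coverage
#'
#' Depth of non-duplicate primary alignments over the C of each CpG.
#'
#' @param alignments A `conv_alignments` object.
#' @param cpg_sites data.frame `chrom`, `pos`.
#' @return Integer coverage vector, one per CpG site.
#' @export
cpg_coverage <- function(alignments, cpg_sites) {
  use <- alignments[alignments$is_primary & !alignments$is_dup, ,
                    drop = FALSE]
  sg <- GenomicRanges::GRanges(cpg_sites$chrom,
                               IRanges::IRanges(cpg_sites$pos,
                                                width = 1L))
  GenomicRanges::countOverlaps(sg, alignment_ranges(use),
                               ignore.strand = TRUE)
}

#' Fraction of CpGs covered at or above thresholds
#'
#' @param coverage Integer coverage per CpG (e.g. from
#'   [cpg_coverage()]).
#' @param thresholds Positive increasing thresholds.
#' @return Named numeric vector of fractions, one per threshold.
#' @export
cpg_coverage_fraction <- function(coverage, thresholds) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  vapply(thresholds, function(t) mean(coverage >= t), numeric(1),
         USE.NAMES = FALSE) -> fr
  names(fr) <- paste0(">=", thresholds)
  fr
}

#' Read length statistics
#'
#' N50 is the largest length `L` such that reads of length `>= L` sum to
#' at least half of all bases.
#'
#' @param lengths Non-negative read lengths.
#' @return list `total_bases`, `n_reads`, `n50`.
#' @export
read_length_stats <- function(lengths) {
  stopifnot(all(lengths >= 0))
  list(total_bases = sum(as.numeric(lengths)), n_reads = length(lengths),
       n50 = n50(lengths))
}

#' N50 of a length vector
#' @param lengths Numeric lengths.
#' @return The N50 (0 for empty input).
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths[!is.na(lengths)])
  if (!length(lengths) || sum(lengths) == 0) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Write capture metrics as TSV and JSON
#' @param metrics An `hs_metrics` list. @param stem Output path stem.
#' @return Paths written, invisibly.
#' @export
write_hs_metrics <- function(metrics, stem) {
  tsv <- paste0(stem, ".tsv"); json <- paste0(stem, ".json")
  df <- data.frame(metric = names(metrics),
                   value = unlist(metrics, use.names = FALSE))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(metrics), json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(tsv, json))
}
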