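#' @importFrom stats rbinom runif rbeta rpois rlnorm setNames p.adjust
#'   wilcox.test complete.cases
#' @importFrom utils head tail write.table read.table adist
NULL

# Conversion spaces of a base-converted (EM-seq) read:
#  "CT" - original-top frame, unmethylated C read as T;
#  "GA" - original-bottom frame, unmethylated C on the bottom strand shows
#         as G->A relative to the top-strand reference.
CONVERSION_SPACES <- c("CT", "GA", "UNKNOWN")

ALLELE_SUPPORT_LEVELS <- c("REF", "ALT", "AMBIGUOUS", "OTHER")

.check_space <- function(space, allow_unknown = FALSE) {
  ok <- space %in% (if (allow_unknown) CONVERSION_SPACES else c("CT", "GA"))
  if (!all(ok)) {
    stop("invalid conversion space: ",
         paste(unique(space[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(space)
}

#' Apply EM-seq base conversion to a single base
#'
#' Enzymatic conversion deaminates unmethylated cytosine to uracil, which is
#' amplified and read as thymine; methylated cytosine is protected.  In the
#' original-top ("CT") frame this turns unmethylated `C` into `T`; in the
#' original-bottom ("GA") frame, read against the top-strand reference, it
#' turns unmethylated-complement `G` into `A`.  All other bases are
#' unchanged.
#'
#' @param base Character vector of bases in `A,C,G,T`.
#' @param space Conversion space, `"CT"` or `"GA"` (recycled).
#' @param methylated Logical vector; is the cytosine at this position
#'   methylated (and therefore protected)?
#' @return Character vector of converted bases.
#' @examples
#' convert_base("C", "CT", methylated = FALSE)  # "T"
#' convert_base("C", "CT", methylated = TRUE)   # "C"
#' convert_base("G", "GA", methylated = FALSE)  # "A"
#' @export
convert_base <- function(base, space, methylated) {
  .check_space(space)
  if (!all(base %in% c("A", "C", "G", "T"))) {
    stop("base must be one of A, C, G, T", call. = FALSE)
  }
  n <- max(length(base), length(space), length(methylated))
  base <- rep_len(base, n)
  space <- rep_len(space, n)
  methylated <- rep_len(methylated, n)
  out <- base
  out[space == "CT" & base == "C" & !methylated] <- "T"
  out[space == "GA" & base == "G" & !methylated] <- "A"
  out
}

#' Possible observations of an allele in a conversion space
#'
#' The closure of [convert_base()] over both methylation states: the set of
#' read bases that a given genomic allele can legitimately produce.  In CT
#' space a genomic `C` may be observed as `C` (methylated) or `T`
#' (converted); in GA space a genomic `G` may be observed as `G` or `A`.
#' Every other allele is observed literally.
#'
#' @param allele Single base, one of `A,C,G,T`.
#' @param space `"CT"` or `"GA"`.
#' @return Character vector of observable bases.
#' @export
observation_set <- function(allele, space) {
  stopifnot(length(allele) == 1L, length(space) == 1L)
  .check_space(space)
  if (!allele %in% c("A", "C", "G", "T")) {
    stop("allele must be one of A, C, G, T", call. = FALSE)
  }
  if (space == "CT" && allele == "C") return(c("C", "T"))
  if (space == "GA" && allele == "G") return(c("G", "A"))
  allele
}

# vectorised membership test: is `observed` producible from `allele`?
.obs_member <- function(observed, allele, space) {
  observed == allele |
    (space == "CT" & allele == "C" & observed == "T") |
    (space == "GA" & allele == "G" & observed == "A")
}

#' Conversion-aware allele support of an observed base
#'
#' Decides whether a base observed in a converted read supports the
#' reference allele, the alternate allele, both (ambiguous under
#' conversion), or neither.  A base supports an allele when it lies in that
#' allele's [observation_set()].  Because conversion collapses C/T (CT
#' space) and G/A (GA space), some variant patterns are inherently
#' indistinguishable in one of the two frames and are reported as
#' `AMBIGUOUS` there.
#'
#' All arguments are recycled to a common length, so the function can score
#' a whole pileup in one call.
#'
#' @param space `"CT"` or `"GA"`.
#' @param ref,alt Reference / alternate alleles (must differ).
#' @param observed Observed read base in `A,C,G,T,N` (`N` is `OTHER`).
#' @return Character vector over `REF, ALT, AMBIGUOUS, OTHER`.
#' @examples
#' allele_support("CT", "C", "T", "T")  # AMBIGUOUS: T reachable from both
#' allele_support("CT", "C", "A", "T")  # REF: converted unmethylated C
#' allele_support("GA", "C", "T", "T")  # ALT: no collapse in GA space
#' @export
allele_support <- function(space, ref, alt, observed) {
  .check_space(space)
  n <- max(length(space), length(ref), length(alt), length(observed))
  space <- rep_len(space, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  observed <- rep_len(observed, n)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  bad <- !observed %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("observed base must be one of A, C, G, T, N", call. = FALSE)
  }
  in_ref <- .obs_member(observed, ref, space)
  in_alt <- .obs_member(observed, alt, space)
  out <- rep("OTHER", n)
  out[in_ref & !in_alt] <- "REF"
  out[!in_ref & in_alt] <- "ALT"
  out[in_ref & in_alt] <- "AMBIGUOUS"
  out[observed == "N"] <- "OTHER"
  out
}

#' Restore the original base at a variant site
#'
#' Maps an observed converted base back to the genomic allele it supports:
#' the reference base for `REF` support, the alternate for `ALT`, and `N`
#' when the observation is ambiguous under conversion or incompatible with
#' both alleles.  This is the per-site rule used to build pseudo reads for
#' phasing.
#'
#' @inheritParams allele_support
#' @return Character vector of restored bases (or `"N"`).
#' @export
restore_base <- function(space, ref, alt, observed) {
  sup <- allele_support(space, ref, alt, observed)
  n <- length(sup)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  out <- rep("N", n)
  out[sup == "REF"] <- ref[sup == "REF"]
  out[sup == "ALT"] <- alt[sup == "ALT"]
  out
}

#' Classify the conversion space of an aligned converted read
#'
#' Fallback classifier for alignments that carry no conversion-space tag:
#' counts reference-`C` positions read as `T` (evidence for the CT frame)
#' and reference-`G` positions read as `A` (GA frame) over aligned,
#' non-variant positions, and requires both a minimum count and a minimum
#' majority ratio before committing to a frame.  Long converted reads carry
#' hundreds of conversion events, so the defaults are generous.
#'
#' @param alignments A `conv_alignments` object (see [read_alignments()]).
#' @param reference A [Biostrings::DNAStringSet] of the reference.
#' @param variant_positions Optional data.frame with `chrom`, `pos`
#'   (1-based) of known variants to exclude from the evidence.
#' @param min_count Minimum count of conversion-consistent mismatches for
#'   the winning frame (default 10).
#' @param ratio Minimum fraction of conversion-consistent mismatches that
#'   must belong to the winning frame (default 0.8).
#' @return Character vector (one element per alignment) over
#'   `CT, GA, UNKNOWN`.
#' @export
classify_read_space <- function(alignments, reference,
                                variant_positions = NULL,
                                min_count = 10, ratio = 0.8) {
  stopifnot(inherits(alignments, "conv_alignments"))
  n <- nrow(alignments)
  if (n == 0L) return(character(0))
  proj <- project_to_reference(alignments)
  refseq <- reference_window(reference, alignments$chrom, alignments$pos,
                             nchar(proj))
  out <- character(n)
  for (i in seq_len(n)) {
    rd <- charToRaw(proj[i])
    rf <- charToRaw(refseq[i])
    use <- rd != charToRaw("-")
    if (!is.null(variant_positions)) {
      vp <- variant_positions$pos[variant_positions$chrom ==
                                    alignments$chrom[i]]
      local <- vp - alignments$pos[i] + 1L
      local <- local[local >= 1L & local <= length(rd)]
      if (length(local)) use[local] <- FALSE
    }
    n_ct <- sum(use & rf == charToRaw("C") & rd == charToRaw("T"))
    n_ga <- sum(use & rf == charToRaw("G") & rd == charToRaw("A"))
    tot <- n_ct + n_ga
    out[i] <- if (tot == 0L) {
      "UNKNOWN"
    } else if (n_ct >= min_count && n_ct / tot >= ratio) {
      "CT"
    } else if (n_ga >= min_count && n_ga / tot >= ratio) {
      "GA"
    } else {
      "UNKNOWN"
    }
  }
  out
}

#' Complement of a base vector
#' @param base Character vector over `A,C,G,T,N`.
#' @return Complemented bases.
#' @export
comp_base <- function(base) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[base])
}
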