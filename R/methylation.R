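#' Call per-CpG methylation from converted alignments
#'
#' Destranded per-CpG counting.  A CT-space read votes through the base it
#' lays over the `C` of a top-strand CpG (`C` = methylated, `T` =
#' unmethylated, anything else uninformative); a GA-space read votes
#' through the base over the paired `G` at the next position (`G` =
#' methylated, `A` = unmethylated).  Both strands are collapsed into one
#' record keyed by the position of the `C`.  Reads with `UNKNOWN` space,
#' non-primary records and flagged duplicates never vote.  CpGs whose `C`
#' or `G` position coincides with a known variant are dropped, because a
#' genotype difference there masquerades as a methylation difference.
#'
#' @param alignments A `conv_alignments` object with known spaces.
#' @param reference [Biostrings::DNAStringSet]; used to validate CpG sites.
#' @param cpg_sites data.frame (`chrom`, `pos` of the C, 1-based).  Default
#'   : all CpGs found in the reference.
#' @param exclude_variants Optional data.frame (`chrom`, `pos`) of variant
#'   positions; CpGs overlapping any are removed.
#' @param groups Optional character/factor, one per alignment row, to
#'   stratify counts (e.g. sample, haplotype `H1`/`H2`, SNV class).  Rows
#'   with `NA` group are skipped.  Default: one group `"all"`.
#' @param min_mapq Minimum MAPQ for a read to vote (default 20).
#' @return A `cpg_table`: data.frame with `chrom`, `pos`, `group`,
#'   `n_meth`, `n_unmeth`, `rate`, sorted by position.
#' @export
call_cpg_methylation <- function(alignments, reference, cpg_sites = NULL,
                                 exclude_variants = NULL, groups = NULL,
                                 min_mapq = 20) {
  stopifnot(inherits(alignments, "conv_alignments"))
  if (is.null(cpg_sites)) cpg_sites <- find_cpg_sites(reference)
  # validate: reference must read C at pos and G at pos+1
  cbase <- reference_window(reference, cpg_sites$chrom, cpg_sites$pos, 2L)
  bad <- cbase != "CG"
  if (any(bad)) {
    stop("not a top-strand CpG at ", cpg_sites$chrom[bad][1], ":",
         cpg_sites$pos[bad][1], call. = FALSE)
  }
  if (!is.null(exclude_variants) && nrow(exclude_variants)) {
    key_c <- paste(cpg_sites$chrom, cpg_sites$pos)
    key_g <- paste(cpg_sites$chrom, cpg_sites$pos + 1L)
    vkey <- paste(exclude_variants$chrom, exclude_variants$pos)
    cpg_sites <- cpg_sites[!(key_c %in% vkey | key_g %in% vkey), ,
                           drop = FALSE]
  }
  if (is.null(groups)) groups <- rep("all", nrow(alignments))
  groups <- as.character(groups)
  use <- alignments$is_primary & !alignments$is_dup &
    alignments$space %in% c("CT", "GA") &
    alignments$mapq >= min_mapq & !is.na(groups)
  aln <- alignments[use, , drop = FALSE]
  groups <- groups[use]
  if (nrow(aln) == 0L || nrow(cpg_sites) == 0L) {
    return(empty_cpg_table())
  }
  # CT reads vote at the C; GA reads vote at the paired G
  is_ga <- aln$space == "GA"
  vote_sites <- rbind(
    data.frame(chrom = cpg_sites$chrom, pos = cpg_sites$pos,
               cpg = seq_len(nrow(cpg_sites)), ga = FALSE),
    data.frame(chrom = cpg_sites$chrom, pos = cpg_sites$pos + 1L,
               cpg = seq_len(nrow(cpg_sites)), ga = TRUE)
  )
  hits <- extract_bases_at(aln, vote_sites)
  if (nrow(hits) == 0L) return(empty_cpg_table())
  ga_site <- vote_sites$ga[hits$site_idx]
  keep <- ga_site == is_ga[hits$aln_idx]
  hits <- hits[keep, , drop = FALSE]
  ga_site <- ga_site[keep]
  meth_base <- ifelse(ga_site, "G", "C")
  unmeth_base <- ifelse(ga_site, "A", "T")
  state <- ifelse(hits$base == meth_base, "M",
                  ifelse(hits$base == unmeth_base, "U", NA))
  ok <- !is.na(state)
  dt <- data.table::data.table(
    cpg = vote_sites$cpg[hits$site_idx[ok]],
    group = groups[hits$aln_idx[ok]],
    m = state[ok] == "M"
  )
  agg <- dt[, list(n_meth = sum(m), n_unmeth = sum(!m)),
            by = c("cpg", "group")]
  out <- data.frame(
    chrom = cpg_sites$chrom[agg$cpg],
    pos = cpg_sites$pos[agg$cpg],
    group = agg$group,
    n_meth = as.integer(agg$n_meth),
    n_unmeth = as.integer(agg$n_unmeth),
    stringsAsFactors = FALSE
  )
  out$rate <- out$n_meth / (out$n_meth + out$n_unmeth)
  out <- out[order(out$chrom, out$pos, out$group), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_table", "data.frame")
  out
}

empty_cpg_table <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    group = character(0), n_meth = integer(0),
                    n_unmeth = integer(0), rate = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("cpg_table", "data.frame")
  out
}

#' Assemble a CpG count table from raw vectors
#' @param chrom,pos,group,n_meth,n_unmeth Column vectors.
#' @return A `cpg_table` data.frame.
#' @export
cpg_table <- function(chrom, pos, group, n_meth, n_unmeth) {
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    group = as.character(group),
                    n_meth = as.integer(n_meth),
                    n_unmeth = as.integer(n_unmeth),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$n_meth >= 0), all(out$n_unmeth >= 0))
  out$rate <- out$n_meth / (out$n_meth + out$n_unmeth)
  out <- out[order(out$chrom, out$pos, out$group), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_table", "data.frame")
  out
}

#' Write a per-CpG methylation bedGraph
#'
#' One row per CpG and group file: `chrom  start(0-based)  end  rate%%
#' n_meth  n_unmeth`, the dialect common to methylation extractors.  One
#' file is written per group, suffixed with the group name when more than
#' one group is present.
#'
#' @param table A `cpg_table`.
#' @param file Output path (used as a stem with multiple groups).
#' @return Character vector of the files written, invisibly.
#' @export
write_cpg_bedgraph <- function(table, file) {
  groups <- unique(table$group)
  paths <- character(0)
  for (g in groups) {
    t <- table[table$group == g, , drop = FALSE]
    path <- if (length(groups) == 1L) file else {
      sub("(\\.bedgraph|\\.bedGraph|\\.bg)?$",
          paste0(".", g, "\\1"), file)
    }
    df <- data.frame(t$chrom, t$pos - 1L, t$pos, round(100 * t$rate, 6),
                     t$n_meth, t$n_unmeth)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a per-CpG methylation bedGraph written by [write_cpg_bedgraph()]
#' @param file Path; @param group Group label to assign (default `"all"`).
#' @return A `cpg_table`.
#' @export
read_cpg_bedgraph <- function(file, group = "all") {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "pct",
                                        "n_meth", "n_unmeth"))
  cpg_table(df$chrom, df$start + 1L, group, df$n_meth, df$n_unmeth)
}
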