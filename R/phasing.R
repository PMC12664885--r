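#' Construct a table of biallelic variants
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic SNVs (`pos`
#'   1-based).
#' @param kind `"HET_SNP"` or `"SOMATIC_SNV"` (recycled).
#' @return data.frame sorted by `chrom`, `pos`, with unique positions per
#'   chromosome enforced.
#' @export
variant_table <- function(chrom, pos, ref, alt, kind = "HET_SNP") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   kind = rep_len(as.character(kind), length(chrom)),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$kind %in% c("HET_SNP", "SOMATIC_SNV")),
            all(df$ref != df$alt),
            all(nchar(df$ref) == 1L), all(nchar(df$alt) == 1L))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(paste(df$chrom, df$pos))) {
    stop("duplicate variant positions", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Build the read-by-variant allele matrix
#'
#' Scores the base that each primary converted alignment lays over each
#' variant position with conversion-aware [allele_support()].  Only primary
#' alignments contribute (supplementary/secondary records of structurally
#' complex reads are excluded so that SVs do not contaminate phasing).
#' `AMBIGUOUS`/`OTHER` cells are recorded but inert downstream.
#'
#' @param alignments A `conv_alignments` object with known conversion
#'   spaces.
#' @param variants A [variant_table()].
#' @param reference Optional reference to bounds-check variants against.
#' @param min_mapq Minimum MAPQ (default 20).
#' @return An `allele_matrix`: data.frame with `read_id`, `aln_idx`,
#'   `variant_idx` (row in `variants`), `observed`, `support`.
#' @export
build_allele_matrix <- function(alignments, variants, reference = NULL,
                                min_mapq = 20) {
  stopifnot(inherits(alignments, "conv_alignments"))
  if (!is.null(reference)) {
    lens <- setNames(width(reference), names(reference))
    bad <- variants$pos < 1L | variants$pos > lens[variants$chrom]
    if (any(is.na(bad)) || any(bad)) {
      stop("variant outside reference bounds", call. = FALSE)
    }
  }
  use <- alignments$is_primary & alignments$space %in% c("CT", "GA") &
    alignments$mapq >= min_mapq
  aln <- alignments[use, , drop = FALSE]
  orig_idx <- which(use)
  hits <- extract_bases_at(aln, variants)
  obs <- hits$base
  obs[!obs %in% c("A", "C", "G", "T")] <- "N"   # deletions etc. -> OTHER
  sup <- if (nrow(hits)) {
    allele_support(aln$space[hits$aln_idx],
                   variants$ref[hits$site_idx],
                   variants$alt[hits$site_idx], obs)
  } else character(0)
  out <- data.frame(
    read_id = aln$read_id[hits$aln_idx],
    aln_idx = orig_idx[hits$aln_idx],
    variant_idx = hits$site_idx,
    observed = obs,
    support = sup,
    stringsAsFactors = FALSE
  )
  attr(out, "n_variants") <- nrow(variants)
  class(out) <- c("allele_matrix", "data.frame")
  out
}

#' Generate pseudo reads with restored variant bases
#'
#' For every read with at least one informative (REF/ALT) variant cell,
#' emits a coordinate-preserving pseudo read: the restored genomic allele
#' at each informative het-variant position and `N` at every other aligned
#' position.  Pseudo reads are laid out in reference space with a
#' single-`M` CIGAR over the original span, so any read-backed phaser can
#' consume the exported SAM.
#'
#' @param matrix An `allele_matrix` from [build_allele_matrix()].
#' @param alignments The `conv_alignments` the matrix was built from.
#' @param variants The [variant_table()] used.
#' @return A `conv_alignments` of pseudo reads.
#' @export
make_pseudo_reads <- function(matrix, alignments, variants) {
  inf <- matrix[matrix$support %in% c("REF", "ALT"), , drop = FALSE]
  if (nrow(inf) == 0L) {
    return(conv_alignments(character(0), integer(0), character(0),
                           integer(0), integer(0), character(0),
                           character(0)))
  }
  keep <- sort(unique(inf$aln_idx))
  aln <- alignments[keep, , drop = FALSE]
  w <- reference_width(aln)
  seqs <- vapply(w, function(n) strrep("N", n), character(1))
  base <- ifelse(inf$support == "REF", variants$ref[inf$variant_idx],
                 variants$alt[inf$variant_idx])
  row_of <- match(inf$aln_idx, keep)
  off <- variants$pos[inf$variant_idx] - aln$pos[row_of] + 1L
  for (k in seq_along(row_of)) {
    substr(seqs[row_of[k]], off[k], off[k]) <- base[k]
  }
  conv_alignments(
    read_id = aln$read_id,
    flag = bitwAnd(aln$flag, 0x10L),   # keep strand bit only
    chrom = aln$chrom, pos = aln$pos, mapq = aln$mapq,
    cigar = paste0(w, "M"), seq = seqs, space = aln$space
  )
}

# informative cells as a data.table with allele value 0 (REF) / 1 (ALT)
.informative_cells <- function(matrix, variants, kind = NULL) {
  inf <- matrix[matrix$support %in% c("REF", "ALT"), , drop = FALSE]
  if (!is.null(kind)) {
    inf <- inf[variants$kind[inf$variant_idx] %in% kind, , drop = FALSE]
  }
  data.table::data.table(
    read_id = inf$read_id,
    variant_idx = inf$variant_idx,
    value = as.integer(inf$support == "ALT")
  )
}

#' Phase heterozygous SNPs into blocks
#'
#' A greedy spanning-forest phaser over the read-linkage graph: variants
#' are nodes; every read that informatively covers a variant pair
#' contributes a cis (same support) or trans (opposite support)
#' observation; an edge's weight is `|cis - trans|` and its orientation
#' `sign(cis - trans)`.  Edges supported by fewer than `min_link` net
#' observations are dropped, a maximum-weight spanning forest is taken,
#' and haplotype bits are propagated from an arbitrary root of each tree.
#' Each tree is one phased block; phase is relative within a block.
#'
#' @param matrix An `allele_matrix`.
#' @param variants The [variant_table()] (needed for `chrom`/`pos` and to
#'   restrict to `HET_SNP` rows).
#' @param min_link Minimum `|cis - trans|` for an edge to survive
#'   (default 2).
#' @return A `phased_blocks` data.frame: `variant_idx`, `block_id`,
#'   `hap1_is_alt` (the phase bit: is the ALT allele on haplotype 1).
#'   Blocks have at least two variants.
#' @export
phase_blocks <- function(matrix, variants, min_link = 2) {
  cells <- .informative_cells(matrix, variants, kind = "HET_SNP")
  empty <- data.frame(variant_idx = integer(0), block_id = integer(0),
                      hap1_is_alt = integer(0))
  class(empty) <- c("phased_blocks", "data.frame")
  if (nrow(cells) < 2L) return(empty)
  # all informative pairs within a read
  value <- NULL; read_id <- NULL; variant_idx <- NULL  # NSE notes
  pairs <- cells[, {
    if (.N >= 2L) {
      i <- rep(seq_len(.N), times = .N) ; j <- rep(seq_len(.N), each = .N)
      k <- i < j
      list(v1 = variant_idx[i[k]], v2 = variant_idx[j[k]],
           cis = as.integer(value[i[k]] == value[j[k]]))
    } else NULL
  }, by = read_id]
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  v1 <- NULL; v2 <- NULL; cis <- NULL
  edges <- pairs[, list(cis = sum(cis), trans = sum(cis == 0L)),
                 by = c("v1", "v2")]
  edges[, `:=`(weight = abs(cis - trans),
               flip = as.integer(cis < trans))]
  weight <- NULL
  edges <- edges[weight >= min_link]
  if (nrow(edges) == 0L) return(empty)
  verts <- sort(unique(c(edges$v1, edges$v2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(edges$v1, verts), to = match(edges$v2, verts),
               weight = edges$weight, flip = edges$flip),
    directed = FALSE,
    vertices = data.frame(name = seq_along(verts))
  )
  forest <- igraph::mst(g, weights = -igraph::E(g)$weight)
  comp <- igraph::components(forest)
  bit <- rep(NA_integer_, length(verts))
  adj <- igraph::as_data_frame(forest, what = "edges")
  adj$from <- as.integer(adj$from); adj$to <- as.integer(adj$to)
  # adjacency lists
  alist <- vector("list", length(verts))
  for (e in seq_len(nrow(adj))) {
    alist[[adj$from[e]]] <- c(alist[[adj$from[e]]], e)
    alist[[adj$to[e]]] <- c(alist[[adj$to[e]]], e)
  }
  for (root in which(!duplicated(comp$membership))) {
    if (!is.na(bit[root])) next
    bit[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (e in alist[[v]]) {
        u <- if (adj$from[e] == v) adj$to[e] else adj$from[e]
        if (is.na(bit[u])) {
          bit[u] <- bitwXor(bit[v], adj$flip[e])
          queue <- c(queue, u)
        }
      }
    }
  }
  # block ids ordered by genomic position of the first variant
  memb <- comp$membership
  first_pos <- tapply(variants$pos[verts], memb, min)
  rank <- match(memb, names(sort(first_pos)))
  out <- data.frame(variant_idx = verts, block_id = as.integer(rank),
                    hap1_is_alt = bit)
  # drop singleton blocks (cannot happen after min_link, but be safe)
  tab <- table(out$block_id)
  out <- out[out$block_id %in% as.integer(names(tab[tab >= 2L])), ,
             drop = FALSE]
  out <- out[order(out$block_id, variants$pos[out$variant_idx]), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phased_blocks", "data.frame")
  out
}

#' Assign reads to haplotypes using phased SNPs
#'
#' Counts, per read, matches to the haplotype-1 versus haplotype-2 alleles
#' at phased het-SNP sites and assigns the majority haplotype when the
#' margin is at least one informative site; ties (or no informative site)
#' are `UNTAGGED`.  A read spanning several blocks is scored on the block
#' where it has the most informative sites.  In `WITH_UNPHASED_SNPS` mode,
#' reads are additionally partitioned at singleton (unphased) het SNPs
#' into per-site allele groups, recovering separation power when phased
#' blocks are short.
#'
#' @param matrix An `allele_matrix`.
#' @param blocks A `phased_blocks` data.frame (internal phaser or an
#'   external phaser's assignment in the same shape).
#' @param variants The [variant_table()].
#' @param mode `"PHASED_ONLY"` (default) or `"WITH_UNPHASED_SNPS"`.
#' @param min_sites Minimum informative phased sites per read (default 1).
#' @return data.frame `read_id`, `haplotype` (`H1`,`H2`,`UNTAGGED`),
#'   `n_informative`, `block_id` (NA when untagged).  In
#'   `WITH_UNPHASED_SNPS` mode, attribute `"site_groups"` holds a
#'   data.frame (`read_id`, `variant_idx`, `allele`) for unphased het
#'   SNPs.
#' @export
haplotag_reads <- function(matrix, blocks, variants,
                           mode = c("PHASED_ONLY", "WITH_UNPHASED_SNPS"),
                           min_sites = 1L) {
  mode <- match.arg(mode)
  cells <- .informative_cells(matrix, variants, kind = "HET_SNP")
  ids <- unique(matrix$read_id)
  out <- data.frame(read_id = ids, haplotype = "UNTAGGED",
                    n_informative = 0L, block_id = NA_integer_,
                    stringsAsFactors = FALSE)
  if (nrow(cells) && nrow(blocks)) {
    ph <- data.table::data.table(variant_idx = blocks$variant_idx,
                                 block_id = blocks$block_id,
                                 bit = blocks$hap1_is_alt)
    dt <- merge(cells, ph, by = "variant_idx")
    if (nrow(dt)) {
      value <- NULL; bit <- NULL; block_id <- NULL; read_id <- NULL
      per_block <- dt[, list(n = .N, h1 = sum(value == bit),
                             h2 = sum(value != bit)),
                      by = c("read_id", "block_id")]
      n <- NULL
      data.table::setorder(per_block, read_id, -n, block_id)
      best <- per_block[!duplicated(per_block$read_id)]
      hap <- ifelse(best$h1 > best$h2, "H1",
                    ifelse(best$h2 > best$h1, "H2", "UNTAGGED"))
      hap[best$n < min_sites] <- "UNTAGGED"
      i <- match(best$read_id, out$read_id)
      out$haplotype[i] <- hap
      out$n_informative[i] <- best$n
      out$block_id[i] <- ifelse(hap == "UNTAGGED", NA_integer_,
                                best$block_id)
    }
  }
  if (mode == "WITH_UNPHASED_SNPS") {
    unphased <- setdiff(which(variants$kind == "HET_SNP"),
                        blocks$variant_idx)
    sg <- cells[cells$variant_idx %in% unphased]
    attr(out, "site_groups") <- data.frame(
      read_id = sg$read_id, variant_idx = sg$variant_idx,
      allele = ifelse(sg$value == 1L, "ALT", "REF"),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Separate reads by somatic SNV carrier status
#'
#' A read is `SNV_PLUS` when it informatively supports the alternate
#' allele at one or more covered somatic SNVs, `SNV_MINUS` when it
#' informatively supports the reference at every covered SNV (and covers
#' at least one), and `UNASSIGNED` when it covers SNVs only ambiguously or
#' not at all.  Reads are pooled genome-wide by default; set `per_locus`
#' to classify relative to a single SNV for locus-restricted comparisons.
#'
#' @param matrix An `allele_matrix` built over (at least) somatic SNVs.
#' @param variants The [variant_table()].
#' @param per_locus Optional variant index; classify only on that SNV.
#' @return data.frame `read_id`, `class`, `n_covered` (informatively
#'   covered SNVs).
#' @export
classify_by_snv <- function(matrix, variants, per_locus = NULL) {
  snv_idx <- which(variants$kind == "SOMATIC_SNV")
  if (!is.null(per_locus)) snv_idx <- intersect(snv_idx, per_locus)
  cells <- .informative_cells(matrix, variants)
  cells <- cells[cells$variant_idx %in% snv_idx]
  ids <- unique(matrix$read_id)
  out <- data.frame(read_id = ids, class = "UNASSIGNED", n_covered = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(cells)) {
    value <- NULL
    agg <- cells[, list(n = .N, any_alt = any(value == 1L)),
                 by = "read_id"]
    i <- match(agg$read_id, out$read_id)
    out$class[i] <- ifelse(agg$any_alt, "SNV_PLUS", "SNV_MINUS")
    out$n_covered[i] <- agg$n
  }
  out
}

#' Switch error rate between two phasings
#'
#' Phase is relative, so the comparison is over consecutive variant pairs:
#' for every pair of adjacent variants (in genomic order) phased in both
#' inputs, inside a single block of each, the pair counts as a switch when
#' the relative orientation of the two phase bits differs between test and
#' truth.  The rate is switches over comparable pairs; block N50 is
#' reported over the genomic spans of the test blocks.  Global flips of
#' any block leave the rate unchanged.
#'
#' @param test,truth `phased_blocks`-shaped data.frames (`variant_idx`,
#'   `block_id`, `hap1_is_alt`).
#' @param variants The shared [variant_table()].
#' @return list with `switch_error_rate` (NA when no comparable pairs),
#'   `n_switches`, `n_comparable_pairs`, `block_n50_length`.
#' @export
switch_error_rate <- function(test, truth, variants) {
  key <- function(b) {
    df <- data.frame(variant_idx = b$variant_idx, block = b$block_id,
                     bit = b$hap1_is_alt)
    df[order(variants$chrom[df$variant_idx],
             variants$pos[df$variant_idx]), , drop = FALSE]
  }
  te <- key(test)
  tr <- key(truth)
  m <- merge(te, tr, by = "variant_idx", suffixes = c("_test", "_truth"))
  m <- m[order(variants$chrom[m$variant_idx],
               variants$pos[m$variant_idx]), , drop = FALSE]
  n_sw <- 0L; n_cmp <- 0L
  if (nrow(m) >= 2L) {
    a <- m[-nrow(m), ]; b <- m[-1, ]
    ok <- variants$chrom[a$variant_idx] == variants$chrom[b$variant_idx] &
      a$block_test == b$block_test & a$block_truth == b$block_truth
    rel_test <- bitwXor(a$bit_test, b$bit_test)
    rel_truth <- bitwXor(a$bit_truth, b$bit_truth)
    n_cmp <- sum(ok)
    n_sw <- sum(ok & rel_test != rel_truth)
  }
  spans <- if (nrow(te)) {
    tapply(variants$pos[te$variant_idx], te$block,
           function(p) diff(range(p)) + 1L)
  } else numeric(0)
  list(
    switch_error_rate = if (n_cmp > 0L) n_sw / n_cmp else NA_real_,
    n_switches = n_sw,
    n_comparable_pairs = n_cmp,
    block_n50_length = n50(as.numeric(spans))
  )
}
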