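#' Coverage-filter a CpG table
#'
#' Keeps only CpG positions where every compared group reaches the
#' minimum coverage.  Sample-versus-sample comparisons conventionally use
#' a floor of five reads per CpG; allele-resolved comparisons, where each
#' haplotype carries roughly half the reads, use three.
#'
#' @param table A `cpg_table` (long format).
#' @param min_cov Minimum `n_meth + n_unmeth` per group (>= 1).
#' @param groups Groups that must pass (default: all groups present).
#' @return Filtered `cpg_table` restricted to `groups`.
#' @export
coverage_filter <- function(table, min_cov, groups = NULL) {
  stopifnot(min_cov >= 1)
  if (is.null(groups)) groups <- unique(table$group)
  t <- table[table$group %in% groups, , drop = FALSE]
  t$cov <- t$n_meth + t$n_unmeth
  key <- paste(t$chrom, t$pos)
  ok_t <- t$cov >= min_cov
  n_groups_ok <- tapply(ok_t, key, sum)
  n_groups <- tapply(rep(1L, nrow(t)), key, sum)
  pass <- names(n_groups_ok)[n_groups_ok == length(groups) &
                               n_groups == length(groups)]
  out <- t[key %in% pass, setdiff(names(t), "cov"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_table", "data.frame")
  out
}

# Mann-Whitney U (two-sided) on two per-CpG rate vectors.  Exact
# distribution for small untied samples, normal approximation with tie
# correction otherwise (per-CpG rates tie heavily at 0 and 1).
.mwu_p <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(1)
  if (length(unique(c(a, b))) == 1L) return(1)  # degenerate: constant
  exact <- length(a) < 8 && length(b) < 8 &&
    !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

# best candidate window within one run of CpG-wise differences d:
# seed with the max-|mean| window of at least min_cpgs sites, then extend
# each flank while the adjacent difference keeps the sign and magnitude,
# which lands boundaries where the signal decays rather than on the
# noisiest core.
.best_window <- function(d, min_cpgs, min_diff) {
  n <- length(d)
  if (n < min_cpgs) return(NULL)
  cs <- c(0, cumsum(d))
  best <- NULL; best_mean <- 0
  for (w in min_cpgs:n) {
    means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    i <- which.max(abs(means))
    if (abs(means[i]) > abs(best_mean)) {
      best_mean <- means[i]
      best <- c(i, i + w - 1L)
    }
  }
  if (is.null(best) || abs(best_mean) < min_diff) return(NULL)
  sgn <- sign(best_mean)
  lo <- best[1]; hi <- best[2]
  while (lo > 1L && sign(d[lo - 1L]) == sgn &&
         abs(d[lo - 1L]) >= min_diff) lo <- lo - 1L
  while (hi < n && sign(d[hi + 1L]) == sgn &&
         abs(d[hi + 1L]) >= min_diff) hi <- hi + 1L
  c(lo, hi)
}

# recursive greedy extraction within one run
.extract_windows <- function(run, min_cpgs, min_diff) {
  out <- list()
  recurse <- function(idx) {
    if (length(idx) < min_cpgs) return()
    d <- run$rate_a[idx] - run$rate_b[idx]
    w <- .best_window(d, min_cpgs, min_diff)
    if (is.null(w)) return()
    sel <- idx[w[1]:w[2]]
    out[[length(out) + 1L]] <<- sel
    if (w[1] > 1L) recurse(idx[1:(w[1] - 1L)])
    if (w[2] < length(idx)) recurse(idx[(w[2] + 1L):length(idx)])
  }
  recurse(seq_len(nrow(run)))
  out
}

#' Call differentially methylated regions between two groups
#'
#' Shared covered CpGs are pre-segmented into candidate runs wherever the
#' distance between adjacent CpGs exceeds `max_gap`.  Within each run a
#' greedy segmentation extracts the strongest contiguous window of at
#' least `min_cpgs` CpGs whose mean methylation difference reaches
#' `min_diff`, tests it with a two-sided Mann-Whitney U on the two
#' per-CpG rate vectors, removes it, and recurses on the flanks.
#' P-values are Benjamini-Hochberg adjusted across all extracted windows
#' genome-wide and regions with `q < q_cut` are reported.
#'
#' @param table A coverage-filtered `cpg_table` containing both groups.
#' @param group_a,group_b The two group labels to compare.
#' @param max_gap Maximum intra-region CpG gap in bp (default 300).
#' @param min_cpgs Minimum CpGs per region (default 10).
#' @param min_diff Minimum absolute mean difference (default 0.1).
#' @param q_cut Reported q-value cut-off (default 0.01).
#' @param all_candidates Also return sub-threshold candidates (default
#'   FALSE).
#' @return data.frame of DMRs: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_cpgs`, `mean_a`, `mean_b`, `mean_diff`
#'   (`mean_a - mean_b`), `p_value`, `q_value`.
#' @export
call_dmrs <- function(table, group_a, group_b, max_gap = 300,
                      min_cpgs = 10, min_diff = 0.1, q_cut = 0.01,
                      all_candidates = FALSE) {
  wide <- merge(
    table[table$group == group_a, c("chrom", "pos", "rate")],
    table[table$group == group_b, c("chrom", "pos", "rate")],
    by = c("chrom", "pos"), suffixes = c("_a", "_b")
  )
  names(wide) <- c("chrom", "pos", "rate_a", "rate_b")
  wide <- wide[order(wide$chrom, wide$pos), , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      mean_diff = numeric(0), p_value = numeric(0),
                      q_value = numeric(0))
  if (nrow(wide) < min_cpgs) return(empty)
  new_run <- c(TRUE, diff(wide$pos) > max_gap |
                 wide$chrom[-1] != wide$chrom[-nrow(wide)])
  run_id <- cumsum(new_run)
  regions <- list()
  for (r in unique(run_id)) {
    run <- wide[run_id == r, , drop = FALSE]
    wins <- .extract_windows(run, min_cpgs, min_diff)
    for (sel in wins) {
      a <- run$rate_a[sel]; b <- run$rate_b[sel]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = run$chrom[1],
        start = min(run$pos[sel]), end = max(run$pos[sel]) + 1L,
        n_cpgs = length(sel),
        mean_a = mean(a), mean_b = mean(b),
        mean_diff = mean(a) - mean(b),
        p_value = .mwu_p(a, b)
      )
    }
  }
  if (!length(regions)) return(empty)
  dmrs <- do.call(rbind, regions)
  dmrs$q_value <- stats::p.adjust(dmrs$p_value, method = "BH")
  if (!all_candidates) {
    dmrs <- dmrs[dmrs$q_value < q_cut, , drop = FALSE]
  }
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  rownames(dmrs) <- NULL
  dmrs
}

#' Merge DMR sets and re-estimate per-sample methylation
#'
#' Unions overlapping or bookended intervals across the per-sample DMR
#' lists, then estimates, per merged interval and per group, the mean of
#' the per-CpG rates passing the coverage floor.  Groups without a single
#' passing CpG in an interval are `NA` (not measurable).  Merging the
#' merged set again is a no-op.
#'
#' @param dmr_sets List of DMR data.frames (as from [call_dmrs()]), or
#'   data.frames with `chrom`, `start`, `end`.
#' @param table A `cpg_table` holding the groups to summarise.
#' @param min_cov Per-CpG coverage floor for the rate means.
#' @param groups Groups to summarise (default all in `table`).
#' @return data.frame `chrom`, `start`, `end`, then one `mean_<group>`
#'   column per group.
#' @export
merge_dmrs <- function(dmr_sets, table, min_cov, groups = NULL) {
  if (is.data.frame(dmr_sets)) dmr_sets <- list(dmr_sets)
  if (is.null(groups)) groups <- unique(table$group)
  grl <- lapply(dmr_sets, function(d) {
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start,
                                                     d$end - 1L))
  })
  merged <- GenomicRanges::reduce(do.call(c, grl))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = BiocGenerics::start(merged),
    end = BiocGenerics::end(merged) + 1L
  )
  t <- table[table$group %in% groups, , drop = FALSE]
  t <- t[t$n_meth + t$n_unmeth >= min_cov, , drop = FALSE]
  tg <- GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$pos,
                                                         width = 1L))
  ov <- GenomicRanges::findOverlaps(tg, merged)
  for (g in groups) out[[paste0("mean_", g)]] <- NA_real_
  if (length(ov)) {
    dt <- data.table::data.table(
      interval = S4Vectors::subjectHits(ov),
      group = t$group[S4Vectors::queryHits(ov)],
      rate = t$rate[S4Vectors::queryHits(ov)]
    )
    rate <- NULL
    agg <- dt[, list(m = mean(rate)), by = c("interval", "group")]
    for (g in groups) {
      a <- agg[agg$group == g]
      out[[paste0("mean_", g)]][a$interval] <- a$m
    }
  }
  out
}

#' Build a DMR difference-filter specification
#'
#' Encodes the per-sample difference predicates applied to a merged DMR
#' table.  Each rule names one or more pairs of group columns; the rule
#' holds for an interval when every pair's absolute difference satisfies
#' `min_diff` (and, if given, stays below `max_diff`).  The special pair
#' `"any"` means: some pair of summarised groups differs by at least
#' `min_diff`.  All rules must hold for an interval to survive.
#'
#' @param rules list of lists with elements `pairs` (list of 2-vectors of
#'   group names, or `"any"`), `min_diff`, `max_diff` (optional).
#' @param require_measurable_in_all Drop intervals with any `NA` group
#'   mean (default TRUE).
#' @param tss_window Optional window for a downstream
#'   [annotate_tss()] step, kept with the spec for bookkeeping
#'   (default 10000).
#' @return A `dmr_filter_spec` list.
#' @export
dmr_filter_spec <- function(rules, require_measurable_in_all = TRUE,
                            tss_window = 10000) {
  for (r in rules) {
    stopifnot(!is.null(r$pairs), !is.null(r$min_diff) ||
                !is.null(r$max_diff))
    for (thr in c(r$min_diff, r$max_diff)) {
      stopifnot(thr >= 0, thr <= 1)
    }
  }
  stopifnot(tss_window >= 0)
  structure(list(rules = rules,
                 require_measurable_in_all = require_measurable_in_all,
                 tss_window = tss_window),
            class = "dmr_filter_spec")
}

#' Apply a difference-filter cascade to a merged DMR table
#'
#' @param merged A merged table from [merge_dmrs()] (columns
#'   `mean_<group>`).
#' @param spec A [dmr_filter_spec()].
#' @return The rows of `merged` passing every rule.
#' @export
apply_filter_cascade <- function(merged, spec) {
  stopifnot(inherits(spec, "dmr_filter_spec"))
  mcols <- grep("^mean_", names(merged), value = TRUE)
  gnames <- sub("^mean_", "", mcols)
  keep <- rep(TRUE, nrow(merged))
  if (spec$require_measurable_in_all) {
    keep <- keep & stats::complete.cases(merged[, mcols, drop = FALSE])
  }
  col <- function(g) {
    cn <- paste0("mean_", g)
    if (!cn %in% names(merged)) {
      stop("unknown sample/group in filter spec: ", g, call. = FALSE)
    }
    merged[[cn]]
  }
  for (r in spec$rules) {
    if (identical(r$pairs, "any") || identical(r$pairs[[1]], "any")) {
      cmb <- utils::combn(gnames, 2, simplify = FALSE)
      anyok <- rep(FALSE, nrow(merged))
      for (p in cmb) {
        d <- abs(col(p[1]) - col(p[2]))
        anyok <- anyok | (!is.na(d) & d >= r$min_diff)
      }
      keep <- keep & anyok
    } else {
      for (p in r$pairs) {
        d <- abs(col(p[1]) - col(p[2]))
        ok <- !is.na(d)
        if (!is.null(r$min_diff)) ok <- ok & d >= r$min_diff
        if (!is.null(r$max_diff)) ok <- ok & d < r$max_diff
        keep <- keep & ok
      }
    }
  }
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate intervals with TSS proximity
#'
#' For each interval: the minimal gap to any transcription start site (0
#' when a TSS lies inside the interval), the nearest gene, and whether
#' the interval lies within `window` bp of a TSS.  Distance is the
#' interval-to-point gap, symmetric and strand-ignored; a TSS exactly
#' `window + 1` bp away is outside.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive-exclusive as produced by [merge_dmrs()]).
#' @param tss data.frame with `gene`, `chrom`, `pos`, and optionally
#'   `strand`.
#' @param window Proximity window in bp (default 10000).
#' @return `intervals` with `nearest_gene`, `tss_distance`,
#'   `within_window` appended.
#' @export
annotate_tss <- function(intervals, tss, window = 10000) {
  stopifnot(nrow(tss) > 0)
  ig <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start,
                                                intervals$end - 1L))
  tg <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(tss$pos, width = 1L))
  nh <- GenomicRanges::distanceToNearest(ig, tg, ignore.strand = TRUE)
  intervals$nearest_gene <- NA_character_
  intervals$tss_distance <- NA_real_
  intervals$within_window <- FALSE
  q <- S4Vectors::queryHits(nh)
  intervals$nearest_gene[q] <- tss$gene[S4Vectors::subjectHits(nh)]
  intervals$tss_distance[q] <- S4Vectors::mcols(nh)$distance
  intervals$within_window <- !is.na(intervals$tss_distance) &
    intervals$tss_distance <= window
  intervals
}

#' Write DMRs as extended BED
#'
#' BED6+ columns: chrom, start (0-based), end, name, -log10 q, strand
#' (`.`), n_cpgs, mean_a, mean_b, mean_diff, p, q.
#'
#' @param dmrs A [call_dmrs()] result. @param file Output path.
#' @return The path, invisibly.
#' @export
write_dmr_bed <- function(dmrs, file) {
  df <- data.frame(
    dmrs$chrom, dmrs$start - 1L, dmrs$end - 1L,
    paste0("DMR", seq_len(nrow(dmrs))),
    round(-log10(pmax(dmrs$q_value, 1e-300)), 4), ".",
    dmrs$n_cpgs, signif(dmrs$mean_a, 6), signif(dmrs$mean_b, 6),
    signif(dmrs$mean_diff, 6), signif(dmrs$p_value, 6),
    signif(dmrs$q_value, 6)
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
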