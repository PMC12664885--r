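#' Load and validate a dual-index sample sheet
#'
#' The sheet is a TSV with columns `sample_id`, `i5`, `i7` describing a
#' unique-dual-index design: all barcodes are the same length, every
#' (i5, i7) pair is unique, and each i5 and each i7 belongs to exactly one
#' sample, so a hit on either index identifies the sample and a
#' cross-sample pair flags index hopping.  The loader warns when any
#' inter-barcode edit distance is small enough (`<= 2 * max_edit`) that
#' error-tolerant matching could collide.
#'
#' @param file TSV path, or a data.frame with the same columns.
#' @param max_edit The edit-distance tolerance the sheet will be used
#'   with (default 1); only used for the collision warning.
#' @return data.frame `sample_id`, `i5`, `i7` with class `sample_sheet`.
#' @export
read_sample_sheet <- function(file, max_edit = 1) {
  sheet <- if (is.data.frame(file)) file else {
    utils::read.table(file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "i5", "i7")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sheet <- sheet[, need]
  sheet$i5 <- toupper(sheet$i5); sheet$i7 <- toupper(sheet$i7)
  bl <- nchar(c(sheet$i5, sheet$i7))
  if (length(unique(bl)) != 1L) {
    stop("all barcodes must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sheet", call. = FALSE)
  }
  all_bc <- c(sheet$i5, sheet$i7)
  if (anyDuplicated(all_bc)) {
    stop("duplicate barcodes across samples", call. = FALSE)
  }
  d <- utils::adist(all_bc)
  diag(d) <- NA
  if (any(d <= 2 * max_edit, na.rm = TRUE)) {
    warning("some barcodes are within ", 2 * max_edit,
            " edits of each other; error-tolerant matching may collide")
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Locate an adapter in a read by semi-global alignment
#'
#' Adapter-global, read-local alignment: the whole adapter must align, the
#' read contributes a local window.  Hits are reported best-first,
#' non-overlapping, down to `min_identity`.  Optionally the reverse
#' complement is searched as well.
#'
#' @param read Read sequence (character).
#' @param adapter Adapter sequence (length >= 10).
#' @param min_identity Minimum identity over the adapter (default 0.75).
#' @param search_rc Also search the reverse complement (default FALSE).
#' @return data.frame `start`, `end` (1-based inclusive on the read),
#'   `identity`, `strand`.
#' @export
locate_adapter <- function(read, adapter, min_identity = 0.75,
                           search_rc = FALSE) {
  stopifnot(nchar(adapter) >= 10)
  pats <- c(`+` = toupper(adapter))
  if (search_rc) pats <- c(pats, `-` = revcomp(toupper(adapter)))
  subj <- toupper(read)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1)
  hits <- data.frame(start = integer(0), end = integer(0),
                     identity = numeric(0),
                     strand = character(0))
  # best hit, then recurse into the flanks, so hits never overlap
  scan <- function(lo, hi, pat, strand) {
    if (hi - lo + 1L < nchar(pat) / 2) return()
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pat),
      Biostrings::DNAString(substring(subj, lo, hi)),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 1, gapExtension = 1
    )
    ident <- Biostrings::nmatch(al) / nchar(pat)
    if (ident < min_identity) return()
    st <- lo + BiocGenerics::start(Biostrings::subject(al)) - 1L
    en <- lo + BiocGenerics::end(Biostrings::subject(al)) - 1L
    hits[nrow(hits) + 1L, ] <<- list(st, en, ident, strand)
    scan(lo, st - 1L, pat, strand)
    scan(en + 1L, hi, pat, strand)
  }
  for (s in names(pats)) scan(1L, nchar(subj), pats[[s]], s)
  hits <- hits[order(-hits$identity, hits$start), , drop = FALSE]
  hits$start <- as.integer(hits$start)
  hits$end <- as.integer(hits$end)
  rownames(hits) <- NULL
  hits
}

#' Split reads at internal adapters
#'
#' Chimeric long reads (ligation or informatic artifacts) carry sequencing
#' adapters internally.  Hits at least `min_internal_offset` from both
#' read ends cut the read; hits closer to an end are trimmed off.
#' Sub-reads shorter than `min_len` are dropped.  Qualities are sliced in
#' register with the sequence.
#'
#' @param seq,qual Character scalars (quality may be `NULL`).
#' @param inner_adapters Character vector of adapter sequences.
#' @param min_identity Minimum adapter identity (default 0.75).
#' @param min_internal_offset Distance from either end below which a hit
#'   trims instead of splitting (default 100).
#' @param min_len Minimum sub-read length to keep (default 200).
#' @return data.frame `seq`, `qual`, `part` (1-based index of sub-read).
#' @export
split_on_internal_adapters <- function(seq, qual = NULL, inner_adapters,
                                       min_identity = 0.75,
                                       min_internal_offset = 100,
                                       min_len = 200) {
  if (is.na(seq) || !nzchar(seq)) stop("malformed record: empty sequence",
                                       call. = FALSE)
  if (!is.null(qual) && nchar(qual) != nchar(seq)) {
    stop("malformed record: quality length differs from sequence",
         call. = FALSE)
  }
  hits <- do.call(rbind, lapply(inner_adapters, function(a) {
    locate_adapter(seq, a, min_identity = min_identity, search_rc = TRUE)
  }))
  L <- nchar(seq)
  keep <- IRanges::IRanges(1L, L)
  if (!is.null(hits) && nrow(hits)) {
    cut <- IRanges::reduce(IRanges::IRanges(hits$start, hits$end))
    keep <- IRanges::setdiff(keep, cut)
  }
  st <- BiocGenerics::start(keep); en <- BiocGenerics::end(keep)
  ok <- (en - st + 1L) >= min_len
  # pieces bounded by a near-end hit are trims, not splits: they are
  # already handled by the setdiff; just enforce min_len
  st <- st[ok]; en <- en[ok]
  data.frame(
    seq = substring(seq, st, en),
    qual = if (is.null(qual)) NA_character_ else substring(qual, st, en),
    part = seq_along(st),
    stringsAsFactors = FALSE
  )
}

# Best barcode hit per end over a set of window strings.  Exact matches
# are found with fixed regexpr; error-tolerant tiers use TRE approximate
# matching (aregexec), where max.distance is the unit-cost edit distance.
# Returns data.table(window_idx, sheet_row, index ("i5"/"i7"), edit, pos).
.scan_barcodes <- function(windows, sheet, max_edit, from_start) {
  res <- list()
  for (r in seq_len(nrow(sheet))) {
    for (ix in c("i5", "i7")) {
      bc <- sheet[[ix]][r]
      for (pat in unique(c(bc, revcomp(bc)))) {
        seen <- rep(FALSE, length(windows))
        for (ed in 0:max_edit) {
          todo <- which(!seen)
          if (!length(todo)) break
          if (ed == 0L) {
            p <- if (from_start) {
              regexpr(pat, windows[todo], fixed = TRUE)
            } else {
              vapply(gregexpr(pat, windows[todo], fixed = TRUE),
                     function(g) g[length(g)], integer(1))
            }
          } else {
            m <- utils::aregexec(pat, windows[todo], fixed = TRUE,
                                 max.distance = ed)
            p <- vapply(m, `[`, integer(1), 1L)
          }
          hit <- which(p > 0L)
          if (length(hit)) {
            res[[length(res) + 1L]] <- data.table::data.table(
              window_idx = todo[hit], sheet_row = r, index = ix,
              edit = ed, pos = as.numeric(p[hit]))
            seen[todo[hit]] <- TRUE
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(data.table::data.table(window_idx = integer(0),
                                  sheet_row = integer(0),
                                  index = character(0), edit = integer(0),
                                  pos = numeric(0)))
  }
  dt <- data.table::rbindlist(res)
  # keep the lowest-edit hit per (window, sheet_row, index)
  data.table::setorderv(dt, c("window_idx", "edit", "pos"),
                        order = c(1L, 1L, if (from_start) 1L else -1L))
  dt[!duplicated(dt[, c("window_idx", "sheet_row", "index")])]
}

# pick the single best hit per window: lowest edit, then leftmost
# (5' windows) / rightmost (3' windows)
.best_per_window <- function(hits, from_start) {
  if (nrow(hits) == 0L) return(hits)
  data.table::setorderv(hits, c("window_idx", "edit", "pos"),
                        order = c(1L, 1L, if (from_start) 1L else -1L))
  hits[!duplicated(hits$window_idx)]
}

#' Demultiplex reads by dual-index barcodes
#'
#' Each barcode (and its reverse complement) is searched with at most
#' `max_edit` edits inside the first and last `window` bases of each
#' read.  Per end, the best hit (lowest edit distance, then closest to
#' the read end) is kept.  A read with one detected barcode, or two from
#' the same sample, is `ASSIGNED`; two barcodes from different samples
#' make an `UNEXPECTED_PAIR` (index hopping) and the read is removed; no
#' hit is `NO_BARCODE`.  With `strict_pair = TRUE`, both ends must agree.
#'
#' @param seqs Character vector of read sequences.
#' @param sheet A [read_sample_sheet()] sheet.
#' @param window Bases searched at each end (default 60; must be at least
#'   the barcode length).
#' @param max_edit Maximum edit distance per barcode (default 1).
#' @param strict_pair Require both ends to yield the same sample
#'   (default FALSE: a single barcode suffices).
#' @return data.frame `outcome` (`ASSIGNED`, `NO_BARCODE`,
#'   `UNEXPECTED_PAIR`), `sample_id`, `edit5`, `edit3` per read.
#' @export
assign_reads <- function(seqs, sheet, window = 60, max_edit = 1,
                         strict_pair = FALSE) {
  blen <- nchar(sheet$i5[1])
  if (window < blen) stop("window smaller than barcode length",
                          call. = FALSE)
  n <- length(seqs)
  out <- data.frame(outcome = rep("NO_BARCODE", n),
                    sample_id = rep(NA_character_, n),
                    edit5 = rep(NA_integer_, n),
                    edit3 = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  L <- nchar(seqs)
  head_w <- substring(seqs, 1L, pmin(window, L))
  tail_w <- substring(seqs, pmax(1L, L - window + 1L), L)
  h5 <- .best_per_window(.scan_barcodes(head_w, sheet, max_edit, TRUE),
                         TRUE)
  h3 <- .best_per_window(.scan_barcodes(tail_w, sheet, max_edit, FALSE),
                         FALSE)
  s5 <- rep(NA_integer_, n); s3 <- rep(NA_integer_, n)
  s5[h5$window_idx] <- h5$sheet_row
  s3[h3$window_idx] <- h3$sheet_row
  out$edit5[h5$window_idx] <- h5$edit
  out$edit3[h3$window_idx] <- h3$edit
  both <- !is.na(s5) & !is.na(s3)
  one <- xor(is.na(s5), is.na(s3))
  agree <- both & s5 == s3
  clash <- both & s5 != s3
  out$outcome[agree] <- "ASSIGNED"
  out$sample_id[agree] <- sheet$sample_id[s5[agree]]
  out$outcome[clash] <- "UNEXPECTED_PAIR"
  if (!strict_pair) {
    out$outcome[one] <- "ASSIGNED"
    only <- ifelse(is.na(s5), s3, s5)
    out$sample_id[one] <- sheet$sample_id[only[one]]
  }
  out
}

#' Demultiplex a FASTQ into per-sample files
#'
#' Runs [assign_reads()] over a FASTQ and writes one FASTQ per sample plus
#' a discard file for unassigned and conflicting reads, so every input
#' read lands in exactly one output stream.  Returns a report whose
#' outcome counts sum to the input read count.
#'
#' @param fastq_in Input FASTQ (optionally gzipped).
#' @param sheet A [read_sample_sheet()] sheet.
#' @param out_dir Output directory (created if missing).
#' @param window,max_edit,strict_pair Passed to [assign_reads()].
#' @return A `demux_report` list: `n_total`, `counts` (per outcome),
#'   `per_sample` (read counts and assignment rate), `assignment_rate`,
#'   `decisions` (per-read data.frame), `files`.
#' @export
demultiplex <- function(fastq_in, sheet, out_dir, window = 60,
                        max_edit = 1, strict_pair = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fq <- read_fastq(fastq_in)
  dec <- assign_reads(fq$seq, sheet, window = window, max_edit = max_edit,
                      strict_pair = strict_pair)
  dec$read_id <- fq$id
  files <- character(0)
  for (s in sheet$sample_id) {
    path <- file.path(out_dir, paste0(s, ".fastq"))
    i <- which(dec$outcome == "ASSIGNED" & dec$sample_id == s)
    write_fastq(fq$id[i], fq$seq[i], fq$qual[i], path)
    files[s] <- path
  }
  disc <- file.path(out_dir, "unassigned.fastq")
  i <- which(dec$outcome != "ASSIGNED")
  write_fastq(fq$id[i], fq$seq[i], fq$qual[i], disc)
  files["unassigned"] <- disc
  counts <- table(factor(dec$outcome, levels = c("ASSIGNED", "NO_BARCODE",
                                                 "UNEXPECTED_PAIR")))
  per_sample <- table(factor(dec$sample_id[dec$outcome == "ASSIGNED"],
                             levels = sheet$sample_id))
  rep <- list(
    n_total = nrow(dec),
    counts = as.list(counts),
    per_sample = as.list(per_sample),
    assignment_rate = if (nrow(dec)) unname(counts[["ASSIGNED"]]) /
      nrow(dec) else NA_real_,
    decisions = dec,
    files = files
  )
  class(rep) <- "demux_report"
  rep
}

#' Write a demultiplexing report as TSV and JSON
#' @param report A `demux_report`.
#' @param stem Output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return Paths written, invisibly.
#' @export
write_demux_report <- function(report, stem) {
  tsv <- paste0(stem, ".tsv")
  json <- paste0(stem, ".json")
  df <- data.frame(metric = c("n_total", names(report$counts),
                              paste0("sample:", names(report$per_sample)),
                              "assignment_rate"),
                   value = c(report$n_total, unlist(report$counts),
                             unlist(report$per_sample),
                             report$assignment_rate))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report[c("n_total", "counts", "per_sample",
                                "assignment_rate")],
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' Read a FASTQ file into a data.frame
#' @param file FASTQ path (gz allowed).
#' @return data.frame `id`, `seq`, `qual`.
#' @export
read_fastq <- function(file) {
  fq <- Biostrings::readDNAStringSet(file, format = "fastq",
                                     with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(fq)$qualities)
  S4Vectors::mcols(fq) <- NULL
  data.frame(
    id = sub("\\s.*$", "", names(fq)),
    seq = as.character(fq),
    qual = quals,
    stringsAsFactors = FALSE
  )
}

#' Write a FASTQ file
#' @param id,seq,qual Per-read vectors.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(id, seq, qual, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  if (length(id)) {
    writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
  }
  invisible(file)
}
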