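ADAPTER <- "TGACTGGAGTTCAGACGTGT"   # 20-mer used across adapter tests

test_that("locate_adapter finds planted and mutated copies", {
  set.seed(10)
  read <- paste0(random_seq(5), ADAPTER, random_seq(80))
  hit <- locate_adapter(read, ADAPTER)
  expect_identical(hit$start[1], 6L)
  expect_identical(hit$end[1], 25L)
  expect_equal(hit$identity[1], 1.0)
  # two substitutions in a 20-mer: identity 0.9 still found
  mut <- ADAPTER
  substr(mut, 4, 4) <- "A"; substr(mut, 15, 15) <- "C"
  expect_false(mut == ADAPTER)
  read2 <- paste0(random_seq(30), mut, random_seq(30))
  hit2 <- locate_adapter(read2, ADAPTER)
  expect_gte(nrow(hit2), 1L)
  expect_gte(hit2$identity[1], 0.9)
})

test_that("locate_adapter sees reverse complements only when asked", {
  set.seed(11)
  rcad <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ADAPTER)))
  read <- paste0(random_seq(40), rcad, random_seq(40))
  expect_identical(nrow(locate_adapter(read, ADAPTER)), 0L)
  hit <- locate_adapter(read, ADAPTER, search_rc = TRUE)
  expect_gte(nrow(hit), 1L)
  expect_identical(hit$strand[1], "-")
})

test_that("split_on_internal_adapters splits, trims and drops", {
  set.seed(12)
  left <- random_seq(400); right <- random_seq(300)
  # identity 0.9: strict enough that random 400-mers carry no
  # spurious hits (the permissive 0.75 default mirrors adapter
  # trimmers that rescan with context)
  id <- 0.9
  # no adapter: read passes through whole
  clean <- split_on_internal_adapters(left, strrep("F", 400), ADAPTER,
                                      min_identity = id, min_len = 100)
  expect_identical(nrow(clean), 1L)
  expect_identical(clean$seq, left)
  expect_identical(clean$qual, strrep("F", 400))
  # internal adapter at the midpoint: two sub-reads, lengths conserved
  chim <- paste0(left, ADAPTER, right)
  parts <- split_on_internal_adapters(chim, NULL, ADAPTER,
                                      min_identity = id, min_len = 100)
  expect_identical(nrow(parts), 2L)
  expect_identical(sum(nchar(parts$seq)),
                   nchar(chim) - nchar(ADAPTER))
  expect_identical(parts$seq[1], left)
  expect_identical(parts$seq[2], right)
  # adapter 10 bp from the 5' end: trimmed, not split
  near <- paste0(substr(left, 1, 10), ADAPTER, right)
  trimmed <- split_on_internal_adapters(near, NULL, ADAPTER,
                                        min_identity = id,
                                        min_internal_offset = 100,
                                        min_len = 100)
  expect_identical(nrow(trimmed), 1L)
  expect_identical(trimmed$seq, right)
  expect_error(split_on_internal_adapters("ACGT", "II", ADAPTER),
               "malformed")
})

test_that("sample sheet validation enforces the unique-dual design", {
  expect_error(read_sample_sheet(data.frame(sample_id = c("A", "B"),
                                            i5 = c("AAAA", "AAAA"),
                                            i7 = c("CCCC", "GGGG"))),
               "duplicate barcodes")
  expect_error(read_sample_sheet(data.frame(sample_id = c("A", "B"),
                                            i5 = c("AAAA", "CCCCC"),
                                            i7 = c("GGGG", "TTTT"))),
               "length")
  expect_warning(read_sample_sheet(data.frame(sample_id = c("A", "B"),
                                              i5 = c("AAAAAAAA",
                                                     "AAAAAAAT"),
                                              i7 = c("CCCCCCCC",
                                                     "GGGGGGGG"))),
                 "collide")
})

test_that("assign_reads follows the window and pairing rules", {
  sheet <- demo_sheet()
  set.seed(13)
  mid <- random_seq(300)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  # exact i5 at the very start, exact i7 (reverse complemented) at the
  # 3' end, both from sample A
  r_ok <- paste0(sheet$i5[1], mid, rc(sheet$i7[1]))
  # i5 of A with i7 of B: index hopping
  r_hop <- paste0(sheet$i5[1], mid, rc(sheet$i7[2]))
  # only barcode copy 70 bp from the end: outside the 60 bp window
  r_far <- paste0(random_seq(70), sheet$i5[1], mid)
  dec <- assign_reads(c(r_ok, r_hop, r_far), sheet, window = 60,
                      max_edit = 1)
  expect_identical(dec$outcome,
                   c("ASSIGNED", "UNEXPECTED_PAIR", "NO_BARCODE"))
  expect_identical(dec$sample_id[1], "A")
  # one barcode suffices by default but not in strict-pair mode
  r_one <- paste0(sheet$i5[2], mid)
  expect_identical(assign_reads(r_one, sheet)$outcome, "ASSIGNED")
  expect_identical(assign_reads(r_one, sheet)$sample_id, "B")
  expect_identical(assign_reads(r_one, sheet,
                                strict_pair = TRUE)$outcome,
                   "NO_BARCODE")
  expect_error(assign_reads(r_ok, sheet, window = 4), "window")
})

test_that("assignment rate is monotone in max_edit and window", {
  sheet <- demo_sheet()
  cfg <- sim_config(seed = 17, genome_length = 1e5, n_targets = 2,
                    n_reads = 300, fragment_n50 = 800,
                    min_fragment = 300, samples = c("A", "B"),
                    sheet = sheet, n_somatic_snvs = 0, n_asm = 0)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  lib <- simulate_library(cfg, ref, v, simulate_methylome(cfg, ref, v))
  # barcode detection (>= 1 hit) is monotone in tolerance and window;
  # the assigned fraction itself can dip when extra tolerance turns a
  # single-hit read into a conflicting pair
  detect <- function(w, e) {
    d <- assign_reads(lib$fastq$seq, sheet, window = w, max_edit = e)
    mean(d$outcome != "NO_BARCODE")
  }
  d_e0 <- detect(60, 0); d_e1 <- detect(60, 1); d_e2 <- detect(60, 2)
  expect_lte(d_e0, d_e1)
  expect_lte(d_e1, d_e2)
  expect_lte(detect(40, 1), detect(80, 1))
  expect_gt(d_e1, 0.9)
})

test_that("demultiplex conserves reads and matches simulator truth", {
  sheet <- demo_sheet()
  # noiseless: every read assigned to its true sample
  cfg0 <- sim_config(seed = 19, genome_length = 1e5, n_targets = 2,
                     n_reads = 400, fragment_n50 = 800,
                     min_fragment = 300, samples = c("A", "B"),
                     sheet = sheet, sub_rate = 0, ins_rate = 0,
                     del_rate = 0, duplicate_rate = 0,
                     n_somatic_snvs = 0, n_asm = 0)
  ref <- simulate_reference(cfg0)
  v <- simulate_variants(cfg0, ref)
  me <- simulate_methylome(cfg0, ref, v)
  lib <- simulate_library(cfg0, ref, v, me)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(lib$fastq$id, lib$fastq$seq, lib$fastq$qual, fq)
  out <- tempfile()
  rep <- demultiplex(fq, sheet, out, max_edit = 0)
  expect_identical(rep$n_total, 400L)
  expect_identical(Reduce(`+`, rep$counts), 400L)
  expect_identical(rep$counts$ASSIGNED, 400L)
  truth <- stats::setNames(lib$reads$sample, lib$reads$read_id)
  dec <- rep$decisions
  expect_identical(sum(dec$sample_id != truth[dec$read_id]), 0L)
  # every read lands in exactly one output file
  n_out <- sum(vapply(rep$files, function(f) {
    length(readLines(f)) / 4L
  }, numeric(1)))
  expect_identical(as.integer(n_out), 400L)
  # planted index hopping is detected read-for-read
  cfg1 <- sim_config(seed = 23, genome_length = 1e5, n_targets = 2,
                     n_reads = 400, fragment_n50 = 800,
                     min_fragment = 300, samples = c("A", "B"),
                     sheet = sheet, sub_rate = 0, ins_rate = 0,
                     del_rate = 0, duplicate_rate = 0,
                     index_hop_rate = 0.1, n_somatic_snvs = 0,
                     n_asm = 0)
  lib1 <- simulate_library(cfg1, ref, v, me)
  dec1 <- assign_reads(lib1$fastq$seq, sheet, max_edit = 0)
  expect_identical(dec1$outcome == "UNEXPECTED_PAIR",
                   lib1$reads$hopped)
  # empty input: zero-count report
  empty <- tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  rep0 <- demultiplex(empty, sheet, tempfile())
  expect_identical(rep0$n_total, 0L)
})
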