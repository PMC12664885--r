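.PIPELINE_MODES <- c("SAMPLE_DMR", "HAPLOTYPE_DMR", "SNV_DMR")

.default_run_config <- function() {
  list(
    mode = "HAPLOTYPE_DMR",
    seed = 1L,
    out_dir = "longemseq_run",
    # provided inputs (all optional when `simulate` is given)
    alignments = NULL, reference = NULL, targets = NULL,
    het_vcf = NULL, snv_vcf = NULL, tss = NULL,
    simulate = NULL,                    # list of sim_config overrides
    demux = list(enabled = FALSE, sheet = NULL, window = 60,
                 max_edit = 1, strict_pair = FALSE),
    phasing = list(min_link = 2, min_sites = 1,
                   haplotag_mode = "WITH_UNPHASED_SNPS"),
    methylation = list(min_mapq = 20),
    dmr = list(max_gap = 300, min_cpgs = 10, min_diff = 0.1,
               q_cut = 0.01, min_cov = NULL,  # NULL: by mode (5 or 3)
               filter_min_diff = 0.5, tss_window = 10000),
    qc = list(enabled = TRUE, use_end = FALSE, end_tolerance = 0)
  )
}

.merge_defaults <- function(user, def, path = "", errs) {
  for (k in names(user)) {
    if (!k %in% names(def)) {
      errs$e <- c(errs$e, paste0("unknown key: ", path, k))
      next
    }
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      if (!is.list(user[[k]])) {
        errs$e <- c(errs$e, paste0(path, k, " must be a block"))
      } else {
        def[[k]] <- .merge_defaults(user[[k]], def[[k]],
                                    paste0(path, k, "."), errs)
      }
    } else {
      def[[k]] <- user[[k]]
    }
  }
  def
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file or a list, fills documented defaults, checks
#' types, modes, thresholds and referenced files, and reports all
#' violations together.
#'
#' @param config Path to a YAML config or a named list.
#' @return A fully defaulted `run_config` list.
#' @export
validate_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    yaml::read_yaml(config)
  } else config
  errs <- new.env(); errs$e <- character(0)
  # `simulate` is a free-form override block; validate it separately
  sim_over <- user$simulate
  user$simulate <- NULL
  cfg <- .merge_defaults(user, .default_run_config(), "", errs)
  cfg$simulate <- sim_over
  if (!cfg$mode %in% .PIPELINE_MODES) {
    errs$e <- c(errs$e, paste0("mode must be one of: ",
                               paste(.PIPELINE_MODES, collapse = ", ")))
  }
  num_pos <- list(c("dmr", "min_cpgs"), c("dmr", "q_cut"),
                  c("dmr", "max_gap"), c("demux", "window"),
                  c("phasing", "min_link"), c("methylation", "min_mapq"))
  for (p in num_pos) {
    v <- cfg[[p[1]]][[p[2]]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      errs$e <- c(errs$e, paste0(p[1], ".", p[2],
                                 " must be a non-negative number"))
    }
  }
  if (!is.null(cfg$dmr$min_cov) &&
      (!is.numeric(cfg$dmr$min_cov) || cfg$dmr$min_cov < 1)) {
    errs$e <- c(errs$e, "dmr.min_cov must be >= 1")
  }
  for (f in c("alignments", "reference", "targets", "het_vcf",
              "snv_vcf", "tss")) {
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) &&
        !file.exists(cfg[[f]])) {
      errs$e <- c(errs$e, paste0(f, ": file not found: ", cfg[[f]]))
    }
  }
  if (is.null(cfg$simulate) &&
      (is.null(cfg$alignments) || is.null(cfg$reference))) {
    errs$e <- c(errs$e,
                "either `simulate` or `alignments` + `reference` needed")
  }
  if (!is.null(cfg$simulate)) {
    tryCatch(do.call(sim_config, c(cfg$simulate,
                                   list(seed = cfg$seed))),
             error = function(e) {
               errs$e <- c(errs$e, conditionMessage(e))
             })
  }
  if (length(errs$e)) {
    stop("invalid run config:\n  ", paste(errs$e, collapse = "\n  "),
         call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)[order(names(unclass(cfg)))]),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the targeted EM-seq analysis pipeline
#'
#' Executes the stages in the order the workflow defines: (optional
#' demultiplexing) — conversion-space assignment — allele matrix —
#' haplotype phasing and read tagging (or SNV-class separation) —
#' per-group CpG methylation — coverage filtering (five reads per CpG
#' for sample comparisons, three for allele-resolved ones) — DMR calling
#' — merge, difference-filter and TSS annotation — capture QC.  Given a
#' `simulate` block, inputs are generated first and the truth tables are
#' kept alongside.  Re-running with the same config and seed reproduces
#' identical outputs.
#'
#' @param config A [validate_config()] result, a list, or a YAML path.
#' @return A `run_report` list: per-stage counts, thresholds used,
#'   wall times, the config hash, plus `results` (in-memory stage
#'   outputs: alignments, phasing, CpG tables, DMRs, QC metrics).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else {
    validate_config(config)
  }
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tick <- function() proc.time()[["elapsed"]]
  stage <- function(name, counts) {
    stages[[name]] <<- c(list(wall_s = round(tick() - t_stage, 3)),
                         counts)
  }
  sim <- NULL
  # --- inputs ---------------------------------------------------------
  t_stage <- tick()
  if (!is.null(cfg$simulate)) {
    scfg <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
    sim <- simulate_experiment(scfg, file.path(out_dir, "sim"))
    reference <- sim$reference$reference
    targets <- sim$reference$targets
    aln <- sim$library$alignments
    het <- variant_table(sim$variants$snps$chrom, sim$variants$snps$pos,
                         sim$variants$snps$ref, sim$variants$snps$alt,
                         "HET_SNP")
    snv <- if (nrow(sim$variants$snvs)) {
      variant_table(sim$variants$snvs$chrom, sim$variants$snvs$pos,
                    sim$variants$snvs$ref, sim$variants$snvs$alt,
                    "SOMATIC_SNV")
    } else NULL
    tss <- sim$reference$tss
    sample_of_read <- setNames(sim$library$reads$sample,
                               sim$library$reads$read_id)
  } else {
    reference <- read_reference(cfg$reference)
    aln <- read_alignments(cfg$alignments)
    targets <- if (!is.null(cfg$targets)) read_targets(cfg$targets)
    het <- if (!is.null(cfg$het_vcf)) read_variants_vcf(cfg$het_vcf)
    snv <- if (!is.null(cfg$snv_vcf)) {
      read_variants_vcf(cfg$snv_vcf, "SOMATIC_SNV")
    }
    tss <- if (!is.null(cfg$tss)) {
      utils::read.table(cfg$tss, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    }
    sample_of_read <- NULL
  }
  stage("input", list(n_alignments = nrow(aln),
                      n_het_snps = if (is.null(het)) 0L else nrow(het),
                      n_snvs = if (is.null(snv)) 0L else nrow(snv)))
  # --- conversion space ----------------------------------------------
  t_stage <- tick()
  unknown <- aln$space == "UNKNOWN"
  if (any(unknown)) {
    aln$space[unknown] <- classify_read_space(aln[unknown, ,
                                                  drop = FALSE],
                                              reference)
  }
  stage("space", list(n_ct = sum(aln$space == "CT"),
                      n_ga = sum(aln$space == "GA"),
                      n_unknown = sum(aln$space == "UNKNOWN")))
  # --- duplicates -----------------------------------------------------
  t_stage <- tick()
  aln <- aln[order(aln$chrom, aln$pos), , drop = FALSE]
  aln <- mark_duplicates(aln, use_end = cfg$qc$use_end,
                         end_tolerance = cfg$qc$end_tolerance)
  stage("duplicates",
        list(duplicate_rate = attr(aln, "duplicate_rate")))
  # --- variants & grouping -------------------------------------------
  variants <- het
  if (!is.null(snv)) {
    variants <- rbind(if (!is.null(het)) het else NULL, snv)
    variants <- variant_table(variants$chrom, variants$pos,
                              variants$ref, variants$alt, variants$kind)
  }
  t_stage <- tick()
  matrix <- build_allele_matrix(aln, variants, reference,
                                min_mapq = cfg$methylation$min_mapq)
  stage("allele_matrix",
        list(n_cells = nrow(matrix),
             n_informative = sum(matrix$support %in% c("REF", "ALT"))))
  mode <- cfg$mode
  groups <- NULL
  phasing_out <- NULL
  t_stage <- tick()
  if (mode == "HAPLOTYPE_DMR") {
    blocks <- phase_blocks(matrix, variants,
                           min_link = cfg$phasing$min_link)
    tags <- haplotag_reads(matrix, blocks, variants,
                           mode = cfg$phasing$haplotag_mode,
                           min_sites = cfg$phasing$min_sites)
    g <- setNames(tags$haplotype, tags$read_id)[aln$read_id]
    g[is.na(g) | g == "UNTAGGED"] <- NA
    groups <- g
    phasing_out <- list(blocks = blocks, tags = tags)
    stage("phasing", list(n_blocks = length(unique(blocks$block_id)),
                          n_phased_snps = nrow(blocks),
                          n_tagged = sum(!is.na(g))))
  } else if (mode == "SNV_DMR") {
    cls <- classify_by_snv(matrix, variants)
    g <- setNames(cls$class, cls$read_id)[aln$read_id]
    g[is.na(g) | g == "UNASSIGNED"] <- NA
    groups <- g
    phasing_out <- list(snv_classes = cls)
    stage("snv_split",
          list(n_plus = sum(g == "SNV_PLUS", na.rm = TRUE),
               n_minus = sum(g == "SNV_MINUS", na.rm = TRUE)))
  } else {
    if (is.null(sample_of_read)) {
      stop("SAMPLE_DMR mode needs per-read sample identities ",
           "(simulate or demultiplex first)", call. = FALSE)
    }
    groups <- unname(sample_of_read[aln$read_id])
    stage("sample_split",
          list(n_samples = length(unique(stats::na.omit(groups)))))
  }
  # --- methylation ----------------------------------------------------
  t_stage <- tick()
  excl <- data.frame(chrom = variants$chrom, pos = variants$pos)
  meth <- call_cpg_methylation(aln, reference,
                               exclude_variants = excl, groups = groups,
                               min_mapq = cfg$methylation$min_mapq)
  min_cov <- cfg$dmr$min_cov
  if (is.null(min_cov)) min_cov <- if (mode == "SAMPLE_DMR") 5L else 3L
  glv <- unique(stats::na.omit(groups))
  filt <- coverage_filter(meth, min_cov, groups = glv)
  stage("methylation", list(n_cpgs = length(unique(paste(meth$chrom,
                                                         meth$pos))),
                            n_covered = length(unique(paste(filt$chrom,
                                                            filt$pos))),
                            min_cov = min_cov))
  # --- DMR ------------------------------------------------------------
  t_stage <- tick()
  dmrs <- merged <- NULL
  if (length(glv) >= 2L) {
    pair <- sort(glv)[1:2]
    dmrs <- call_dmrs(filt, pair[1], pair[2],
                      max_gap = cfg$dmr$max_gap,
                      min_cpgs = cfg$dmr$min_cpgs,
                      min_diff = cfg$dmr$min_diff,
                      q_cut = cfg$dmr$q_cut)
    write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    if (nrow(dmrs)) {
      merged <- merge_dmrs(dmrs, meth, min_cov, groups = glv)
      spec <- dmr_filter_spec(
        rules = list(list(pairs = "any",
                          min_diff = cfg$dmr$filter_min_diff)),
        tss_window = cfg$dmr$tss_window
      )
      merged <- apply_filter_cascade(merged, spec)
      if (!is.null(tss) && nrow(tss)) {
        merged <- annotate_tss(merged, tss, window = cfg$dmr$tss_window)
        merged <- merged[merged$within_window, , drop = FALSE]
      }
    }
  }
  stage("dmr", list(n_dmrs = if (is.null(dmrs)) 0L else nrow(dmrs),
                    n_filtered = if (is.null(merged)) 0L else
                      nrow(merged),
                    q_cut = cfg$dmr$q_cut))
  # --- QC -------------------------------------------------------------
  t_stage <- tick()
  qc <- NULL
  if (isTRUE(cfg$qc$enabled) && !is.null(targets) && length(targets)) {
    qc <- hs_metrics(aln, targets, sum(as.numeric(width(reference))))
    write_hs_metrics(qc, file.path(out_dir, "hs_metrics"))
    stage("qc", list(mean_bait_coverage = qc$mean_bait_coverage,
                     fold_enrichment = qc$fold_enrichment,
                     on_target_read_rate = qc$on_target_read_rate))
  }
  write_cpg_bedgraph(filt, file.path(out_dir, "cpg_methylation.bedgraph"))
  report <- list(
    mode = mode,
    seed = cfg$seed,
    config_hash = .config_hash(cfg),
    tool_version = as.character(utils::packageVersion("longemseq")),
    stages = stages,
    wall_s = round(tick() - t0, 3),
    results = list(alignments = aln, matrix = matrix,
                   phasing = phasing_out, methylation = meth,
                   filtered = filt, dmrs = dmrs, merged = merged,
                   qc = qc, sim = sim)
  )
  class(report) <- "run_report"
  jsonlite::write_json(
    report[c("mode", "seed", "config_hash", "tool_version", "stages",
             "wall_s")],
    file.path(out_dir, "run_report.json"), auto_unbox = TRUE,
    digits = NA, force = TRUE
  )
  report
}
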