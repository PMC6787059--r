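write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

log_line <- function(outdir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
  cat(msg, "\n", sep = "", file = file.path(outdir, "log.txt"), append = TRUE)
  invisible(msg)
}

#' Validate a run configuration
#'
#' A run configuration is a named list combining [sim_config()] fields with
#' workspace keys (`outdir`, `preset_name`, `oligo_top`, `plasmid_len`,
#' `replicates`). Unknown keys are rejected.
#'
#' @param cfg named list (e.g. loaded from YAML with [yaml::read_yaml()]).
#' @return a list with elements `sim` (a [sim_config()]) and `workspace`.
#' @export
run_config <- function(cfg = list()) {
  ws_keys <- c("outdir", "preset_name", "oligo_top", "plasmid_len",
               "replicates")
  sim_keys <- setdiff(names(formals(sim_config)), "preset")
  unknown <- setdiff(names(cfg), c(ws_keys, sim_keys, "preset"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ws <- cfg[intersect(names(cfg), ws_keys)]
  if (is.null(ws$preset_name)) ws$preset_name <- "IE"
  sim_args <- cfg[intersect(names(cfg), sim_keys)]
  sim_args$preset <- system_preset(ws$preset_name)
  list(sim = do.call(sim_config, sim_args), workspace = ws)
}

locus_meta <- function(ref, cfg) {
  list(preset = cfg$preset$name,
       contig = ref$pps$protospacer$contig,
       genome_len = cfg$genome_len,
       leader = ref$locus$leader,
       repeat_seq = ref$locus$repeat_seq,
       spacers = as.list(ref$locus$spacers),
       pps = list(start = ref$pps$protospacer$start,
                  end = ref$pps$protospacer$end,
                  strand = ref$pps$protospacer$strand,
                  pam_start = ref$pps$pam_interval$start,
                  pam_end = ref$pps$pam_interval$end))
}

load_locus_meta <- function(run_dir) {
  meta <- yaml::read_yaml(file.path(run_dir, "locus.yaml"))
  preset <- system_preset(meta$preset)
  ps <- interval(meta$contig, meta$pps$start, meta$pps$end, meta$pps$strand)
  pam <- interval(meta$contig, meta$pps$pam_start, meta$pps$pam_end,
                  meta$pps$strand)
  list(meta = meta, preset = preset, pps = pps(ps, pam),
       locus = crispr_locus(meta$leader, meta$repeat_seq,
                            unlist(meta$spacers), preset))
}

#' Simulation stage runner
#'
#' Generates the reference, protospacer sites, prespacer ground truth and
#' FASTQ libraries into `outdir` (FASTA, FASTQ, TSV manifests, YAML locus
#' description, JSON summary). Deterministic for a fixed config.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects.
#' @export
run_simulate <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_reference(cfg)
  write_genome(ref$genome, file.path(outdir, "genome.fasta"))
  yaml::write_yaml(locus_meta(ref, cfg), file.path(outdir, "locus.yaml"))
  sites <- select_protospacers(ref$genome, ref$pps, cfg)
  write_tsv(sites, file.path(outdir, "sites.tsv"))
  truth <- emit_duplexes(sites, cfg)
  write_tsv(truth, file.path(outdir, "truth_duplexes.tsv"))
  frag <- synthesize_fragseq_reads(truth, ref$genome, cfg, ref$pps)
  write_fastq(frag$reads, file.path(outdir, "fragseq.fastq"))
  write_tsv(frag$manifest$molecules, file.path(outdir, "molecules.tsv"))
  arr <- synthesize_array_amplicons(sites, ref$locus, ref$genome, cfg)
  write_fastq(arr$reads, file.path(outdir, "arrays.fastq"))
  write_tsv(arr$manifest, file.path(outdir, "arrays_manifest.tsv"))
  summary <- list(stage = "simulate", seed = cfg$seed,
                  preset = cfg$preset$name,
                  n_sites = nrow(sites), n_duplex_molecules = cfg$n_duplexes,
                  n_fragseq_reads = nrow(frag$reads),
                  n_array_reads = nrow(arr$reads))
  jsonlite::write_json(summary, file.path(outdir, "simulate_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(outdir, "simulate: seed ", cfg$seed, ", ",
           nrow(frag$reads), " FragSeq reads, ", nrow(arr$reads),
           " array reads")
  invisible(list(ref = ref, sites = sites, truth = truth, fragseq = frag,
                 arrays = arr))
}

#' FragSeq analysis stage runner
#'
#' Runs the full fragment pipeline on `fragseq.fastq` in `run_dir`
#' (masking, parsing, consensus, unique alignment), classifies fragments,
#' pairs duplexes, and infers the PAM from the 5'-anchored PFM of the
#' modal short-strand length class. Writes TSV/BED outputs and a JSON
#' summary.
#'
#' @param run_dir directory holding `fragseq.fastq`, `genome.fasta`,
#'   `locus.yaml` (as produced by [run_simulate()]).
#' @return invisibly, a list with the fragment table, duplex calls, PFM
#'   and PAM call.
#' @export
run_fragseq <- function(run_dir) {
  lm <- load_locus_meta(run_dir)
  genome <- read_genome(file.path(run_dir, "genome.fasta"))
  reads <- read_fastq(file.path(run_dir, "fragseq.fastq"))
  pipe <- fragseq_pipeline(reads, genome)
  tab <- classify_fragments(pipe$table, lm$pps, lm$preset)
  write_tsv(tab, file.path(run_dir, "fragment_table.tsv"))
  bed <- data.frame(tab$contig, tab$start, tab$end,
                    paste0("frag", seq_len(nrow(tab))), tab$abundance,
                    tab$strand)
  utils::write.table(bed, file.path(run_dir, "fragments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  calls <- pair_duplexes(tab, genome, lm$preset)
  write_tsv(calls, file.path(run_dir, "duplex_calls.tsv"))
  short_mode <- modal_value(calls$short_len, calls$support_short)
  pfm <- end_pfm(tab, genome, "five_prime",
                 length_range = c(short_mode, short_mode),
                 window = lm$preset$logo_window_5p)
  utils::write.table(pfm$counts, file.path(run_dir, "pfm_5p.tsv"),
                     sep = "\t", quote = FALSE)
  pam <- tryCatch(call_pam(pfm), error = function(e) NULL)
  summary <- list(stage = "fragseq",
                  accounting = as.list(pipe$accounting),
                  n_fragment_rows = nrow(tab),
                  n_duplex_calls = nrow(calls),
                  modal_short_len = short_mode,
                  modal_overhang = modal_value(calls$overhang,
                                               calls$support_short),
                  pam_motifs = if (is.null(pam)) list() else
                    pam$motifs$motif)
  jsonlite::write_json(summary, file.path(run_dir, "fragseq_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(run_dir, "fragseq: ", pipe$accounting[["reads_in"]],
           " reads -> ", pipe$accounting[["molecules"]], " molecules -> ",
           pipe$accounting[["aligned"]], " aligned; ", nrow(calls),
           " duplex calls")
  invisible(list(table = tab, calls = calls, pfm = pfm, pam = pam,
                 accounting = pipe$accounting))
}

# Abundance-weighted mode; NA for empty input.
modal_value <- function(x, w = NULL) {
  if (length(x) == 0L) return(NA_integer_)
  if (is.null(w)) w <- rep(1, length(x))
  tot <- tapply(w, x, sum)
  as.integer(names(tot)[which.max(tot)])
}

#' Spacer-acquisition analysis stage runner
#'
#' Extracts spacers from the array amplicon reads, maps them exactly and
#' uniquely, applies the slippage/flippage filter, and writes per-spacer
#' records, a BED of retained protospacers and the summary statistics.
#'
#' @param run_dir directory holding `arrays.fastq`, `genome.fasta`,
#'   `locus.yaml`.
#' @return invisibly, a list with `records` and `stats`.
#' @export
run_spacers <- function(run_dir) {
  lm <- load_locus_meta(run_dir)
  genome <- read_genome(file.path(run_dir, "genome.fasta"))
  reads <- read_fastq(file.path(run_dir, "arrays.fastq"))
  masked <- mask_low_quality(reads, 20L)
  sp <- unlist(lapply(masked$seq, extract_spacers,
                      repeat_seq = lm$locus$repeat_seq))
  recs <- map_spacers(sp, genome, lm$preset)
  recs <- filter_slippage_flippage(recs)
  write_tsv(recs, file.path(run_dir, "spacer_records.tsv"))
  st <- spacer_stats(recs, lm$pps, lm$preset, lm$meta$genome_len)
  keep <- recs$status == "mapped" & !recs$slippage & !recs$flippage
  bed <- data.frame(recs$contig[keep], recs$start[keep], recs$end[keep],
                    recs$seq[keep], 0L, recs$strand[keep])
  utils::write.table(bed, file.path(run_dir, "protospacers.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(stage = "spacers", n_reads = nrow(reads),
         accounting = as.list(st$accounting),
         n_retained = st$n_retained, pam_fraction = st$pam_fraction,
         by_class = as.list(st$by_class), by_side = as.list(st$by_side)),
    file.path(run_dir, "spacers_summary.json"), auto_unbox = TRUE,
    digits = NA)
  log_line(run_dir, "spacers: ", nrow(reads), " reads -> ",
           st$accounting[["extracted"]], " spacers -> ", st$n_retained,
           " retained (PAM fraction ",
           sprintf("%.3f", st$pam_fraction), ")")
  invisible(list(records = recs, stats = st))
}

#' Prespacer-efficiency assay stage runner
#'
#' Simulates (or loads) assay amplicons, applies the Phred-14 read filter
#' and repeat requirement, extracts and source-assigns spacers, classifies
#' processing status and reports integration efficiency.
#'
#' @param run_dir run directory (for the locus and outputs).
#' @param oligo_top top-strand oligo sequence.
#' @param params assay simulation parameters (see
#'   [synthesize_assay_reads()]); ignored when `fastq` is given.
#' @param fastq optional path to an existing assay FASTQ.
#' @param plasmid optional [genome_ref()] of the resident plasmid.
#' @param seed seed for simulation.
#' @return invisibly, a list with `records` and `result`.
#' @export
run_assay <- function(run_dir, oligo_top, params = list(), fastq = NULL,
                      plasmid = NULL, seed = 1L) {
  lm <- load_locus_meta(run_dir)
  genome <- read_genome(file.path(run_dir, "genome.fasta"))
  if (is.null(fastq)) {
    params$locus <- lm$locus
    sim <- synthesize_assay_reads(oligo_top, params, seed = seed)
    write_fastq(sim$reads, file.path(run_dir, "assay.fastq"))
    reads <- sim$reads
  } else {
    reads <- read_fastq(fastq)
  }
  filt <- filter_assay_reads(reads, lm$locus$repeat_seq)
  recs <- extract_and_map_oligo_spacers(filt, genome, plasmid, oligo_top,
                                        lm$locus$repeat_seq)
  recs$processing <- ifelse(recs$source == "oligo",
                            classify_processing(recs$seq, oligo_top),
                            "other")
  res <- assay_efficiency(recs, nrow(filt))
  write_tsv(recs, file.path(run_dir, "assay_spacers.tsv"))
  jsonlite::write_json(
    c(list(stage = "assay",
           accounting = as.list(attr(filt, "accounting"))),
      unclass(res)),
    file.path(run_dir, "assay_summary.json"), auto_unbox = TRUE, digits = NA)
  log_line(run_dir, "assay: ", nrow(reads), " reads -> ", nrow(filt),
           " scored; direct ", sprintf("%.2f", res$pct_direct), "%")
  invisible(list(records = recs, result = res))
}

#' Coverage stage runner
#'
#' Simulates a genomic-DNA library with PPS-region depletion, computes the
#' binned normalised coverage track and its loess smoothing, and writes
#' TSV/bedGraph outputs.
#'
#' @param run_dir run directory.
#' @param seed seed for the depth simulation.
#' @return invisibly, the smoothed track.
#' @export
run_coverage <- function(run_dir, seed = 1L) {
  lm <- load_locus_meta(run_dir)
  genome <- read_genome(file.path(run_dir, "genome.fasta"))
  hits <- simulate_genomic_depth(genome, lm$pps, seed = seed)
  track <- binned_coverage(hits, lm$meta$genome_len)
  track <- smooth_coverage(track)
  write_tsv(data.frame(bin_start = track$bin_start, value = track$values,
                       smoothed = track$smoothed, ci_low = track$ci_low,
                       ci_high = track$ci_high),
            file.path(run_dir, "coverage.tsv"))
  write_bedgraph(track, lm$meta$contig,
                 file.path(run_dir, "coverage.bedgraph"))
  jsonlite::write_json(
    list(stage = "coverage", n_bins = length(track$values),
         min_bin_start = track$bin_start[which.min(track$smoothed)]),
    file.path(run_dir, "coverage_summary.json"), auto_unbox = TRUE,
    digits = NA)
  log_line(run_dir, "coverage: ", length(track$values), " bins")
  invisible(track)
}

#' Compose a run report
#'
#' Collects the per-stage summary JSON files of a run directory into a
#' single machine-readable report (`report.json`) and a short human
#' summary (`report.md`); every number is re-derivable from the stage
#' outputs. Regeneration is idempotent.
#'
#' @param run_dir run directory with completed stage outputs.
#' @return invisibly, the report list.
#' @export
run_report <- function(run_dir) {
  files <- list.files(run_dir, pattern = "_summary\\.json$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no stages found in ", run_dir,
         " (no *_summary.json present)")
  stages <- lapply(files, jsonlite::read_json)
  names(stages) <- vapply(stages, function(s) s$stage %||% "unknown", "")
  report <- list(run_dir = run_dir, stages = stages)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Run report", "",
          vapply(names(stages), function(nm) {
            s <- stages[[nm]]
            paste0("- **", nm, "**: ",
                   paste(vapply(setdiff(names(s), c("stage", "accounting")),
                                function(k) paste0(k, " = ",
                                  paste(unlist(s[[k]]), collapse = ",")),
                                ""), collapse = "; "))
          }, ""))
  writeLines(md, file.path(run_dir, "report.md"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end runner
#'
#' Chains simulation, FragSeq analysis, spacer analysis, coverage and
#' report generation under one configuration.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @return invisibly, the report list.
#' @export
run_all <- function(cfg, outdir) {
  run_simulate(cfg, outdir)
  run_fragseq(outdir)
  run_spacers(outdir)
  run_coverage(outdir, seed = cfg$seed + 5L)
  run_report(outdir)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `fragseq`, `spacers`, `assay`, `coverage`,
#' `report`, `all`. Common flags: `--out DIR` (run directory), `--config
#' FILE` (YAML run configuration), `--seed N`, `--preset IE|IF`,
#' `--oligo SEQ` (assay). Unknown flags are a usage error.
#'
#' @param argv character vector of arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status (0 on success), invisibly.
#' @export
fragseq_cli <- function(argv) {
  usage <- paste(
    "usage: fragseqr <simulate|fragseq|spacers|assay|coverage|report|all>",
    "[--out DIR] [--config FILE] [--seed N] [--preset IE|IF] [--oligo SEQ]")
  status <- tryCatch({
    if (length(argv) == 0L) stop(usage, call. = FALSE)
    cmd <- argv[[1L]]
    if (!cmd %in% c("simulate", "fragseq", "spacers", "assay", "coverage",
                    "report", "all"))
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
    opts <- list(out = "fragseqr_run", config = NULL, seed = NULL,
                 preset = NULL, oligo = NULL)
    args <- argv[-1L]
    i <- 1L
    while (i <= length(args)) {
      key <- sub("^--", "", args[[i]])
      if (!grepl("^--", args[[i]]) || !key %in% names(opts))
        stop("unknown flag '", args[[i]], "'\n", usage, call. = FALSE)
      if (i + 1L > length(args)) stop("flag --", key, " needs a value",
                                      call. = FALSE)
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
    raw <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
    if (!is.null(opts$seed)) raw$seed <- as.integer(opts$seed)
    if (!is.null(opts$preset)) raw$preset_name <- opts$preset
    rc <- run_config(raw)
    seed <- rc$sim$seed
    switch(cmd,
      simulate = run_simulate(rc$sim, opts$out),
      fragseq = run_fragseq(opts$out),
      spacers = run_spacers(opts$out),
      assay = {
        if (is.null(opts$oligo) && is.null(rc$workspace$oligo_top))
          stop("assay requires --oligo or config key oligo_top",
               call. = FALSE)
        run_assay(opts$out, opts$oligo %||% rc$workspace$oligo_top,
                  seed = seed)
      },
      coverage = run_coverage(opts$out, seed = seed),
      report = run_report(opts$out),
      all = run_all(rc$sim, opts$out))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    if (grepl("usage:", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}
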