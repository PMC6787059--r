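#' Locate the properly processed core of a prespacer oligo
#'
#' A prespacer oligo is cut between AA and G before integration; the
#' properly processed spacer is the 33-nt core beginning at the G that
#' follows the oligo's AA dinucleotide. This helper finds the first
#' `AAG` in the top strand with a full 33-nt core downstream of the AA.
#'
#' @param oligo_top top-strand oligo sequence.
#' @param core_len processed core length (default 33).
#' @return list with `seq` (the core) and `g_pos` (1-based position of the
#'   core's first base, the G).
#' @export
oligo_core <- function(oligo_top, core_len = 33L) {
  check_dna(oligo_top)
  hits <- gregexpr("AAG", oligo_top, fixed = TRUE)[[1L]]
  hits <- hits[hits > 0L]
  g_pos <- hits + 2L
  g_pos <- g_pos[g_pos + core_len - 1L <= nchar(oligo_top)]
  if (length(g_pos) == 0L)
    stop("oligo has no AA|G processing site with a full ", core_len,
         "-nt core")
  g <- g_pos[1L]
  list(seq = substr(oligo_top, g, g + core_len - 1L), g_pos = g)
}

#' Filter prespacer-assay reads
#'
#' Removes any read containing a base with Phred quality below `qmin`
#' (default 14), then requires at least one CRISPR repeat site.
#'
#' @param reads raw read data.frame.
#' @param repeat_seq the repeat sequence.
#' @param qmin Phred threshold.
#' @param max_mm repeat-matching mismatch tolerance.
#' @return the kept reads, with an `"accounting"` attribute (named counts:
#'   `reads_in`, `low_quality`, `no_repeat`, `kept`).
#' @export
filter_assay_reads <- function(reads, repeat_seq, qmin = 14L, max_mm = 2L) {
  n <- nrow(reads)
  lowq <- vapply(reads$qual, function(q) any(utf8ToInt(q) - 33L < qmin),
                 logical(1L), USE.NAMES = FALSE)
  surv <- reads[!lowq, , drop = FALSE]
  has_rep <- vapply(surv$seq, function(s)
    length(find_repeat_sites(s, repeat_seq, max_mm)) >= 1L, logical(1L),
    USE.NAMES = FALSE)
  out <- surv[has_rep, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "accounting") <- c(reads_in = n, low_quality = sum(lowq),
                               no_repeat = sum(!has_rep), kept = nrow(out))
  out
}

#' Extract and source-assign oligo-assay spacers
#'
#' Extracts newly acquired spacers from expanded arrays (reads with two or
#' more repeats) and assigns each to the source -- transforming oligo,
#' genome, or plasmid -- giving the best match with at most `max_mm`
#' mismatches. Oligo matching is strand-aware. If two distinct sources tie
#' at the minimum mismatch count the spacer is assigned `unknown`
#' (no precedence is applied).
#'
#' @param reads filtered reads ([filter_assay_reads()]).
#' @param genome a [genome_ref()].
#' @param plasmid a [genome_ref()] (or NULL).
#' @param oligo_top top-strand oligo sequence.
#' @param repeat_seq the repeat sequence.
#' @param max_mm mismatch tolerance (default 2).
#' @return data.frame with one row per extracted spacer: `read_id`, `seq`,
#'   `source` ("oligo"/"genome"/"plasmid"/"unknown"), `orientation` ("+"
#'   if the spacer matches the oligo top strand, "-" for its reverse
#'   complement, NA otherwise).
#' @export
extract_and_map_oligo_spacers <- function(reads, genome, plasmid, oligo_top,
                                          repeat_seq, max_mm = 2L) {
  recs <- list()
  for (i in seq_len(nrow(reads))) {
    sps <- extract_spacers(reads$seq[i], repeat_seq)
    if (length(sps))
      recs[[length(recs) + 1L]] <- data.frame(read_id = reads$id[i],
                                              seq = sps,
                                              stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L)
    return(data.frame(read_id = character(), seq = character(),
                      source = character(), orientation = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  oligo_ref <- genome_ref(c(oligo = oligo_top))
  best_mm <- function(sp, ref) {
    # minimum mismatch count of an ungapped end-to-end hit on either strand
    best <- Inf
    for (ctg in names(ref$seqs)) {
      subj <- DNAString(ref$seqs[[ctg]])
      for (pat in c(sp, revcomp(sp))) {
        m <- matchPattern(DNAString(pat), subj, max.mismatch = max_mm,
                          fixed = TRUE)
        if (length(m)) {
          mm <- min(vapply(start(m), function(st)
            neditStartingAt(DNAString(pat), subj, starting.at = st),
            integer(1L)))
          best <- min(best, mm)
        }
      }
    }
    best
  }
  uniq <- unique(out$seq)
  src <- vapply(uniq, function(sp) {
    d <- c(oligo = best_mm(sp, oligo_ref),
           genome = best_mm(sp, genome),
           plasmid = if (is.null(plasmid)) Inf else best_mm(sp, plasmid))
    if (!any(is.finite(d))) return("unknown")
    winners <- names(d)[d == min(d)]
    if (length(winners) == 1L) winners else "unknown"
  }, "")
  ori <- vapply(uniq, function(sp) {
    fwd <- length(matchPattern(DNAString(sp), DNAString(oligo_top),
                               max.mismatch = max_mm, fixed = TRUE)) > 0L
    rev <- length(matchPattern(DNAString(revcomp(sp)), DNAString(oligo_top),
                               max.mismatch = max_mm, fixed = TRUE)) > 0L
    if (fwd && !rev) "+" else if (rev && !fwd) "-" else NA_character_
  }, "")
  out$source <- unname(src[match(out$seq, uniq)])
  out$orientation <- ifelse(out$source == "oligo",
                            unname(ori[match(out$seq, uniq)]),
                            NA_character_)
  row.names(out) <- NULL
  out
}

#' Classify the processing status of an oligo-derived spacer
#'
#' A spacer is properly processed iff it is exactly the 33-nt core
#' beginning at the G that follows the oligo's AA dinucleotide (direct
#' orientation), or exactly the reverse complement of that core (reverse
#' orientation); anything else is `other`.
#'
#' @param seq spacer sequence(s).
#' @param oligo_top top-strand oligo sequence.
#' @return character vector over \{"properly_processed_direct",
#'   "properly_processed_reverse", "other"\}.
#' @export
classify_processing <- function(seq, oligo_top) {
  core <- oligo_core(oligo_top)$seq
  ifelse(seq == core, "properly_processed_direct",
         ifelse(seq == revcomp(core), "properly_processed_reverse", "other"))
}

#' Prespacer integration efficiency
#'
#' Percentages of scored arrays containing a properly processed
#' oligo-derived spacer in direct or reverse orientation. "Arrays scored"
#' is the number of filtered reads spanning the leader-repeat junction
#' (all filtered reads, for the amplicon design simulated here).
#'
#' @param records classified spacer records: data.frame with columns
#'   `source` and `processing` (from [classify_processing()]).
#' @param n_arrays_scored number of scored arrays (> 0).
#' @return list of class `"assay_result"` with counts `n_arrays_scored`,
#'   `n_direct`, `n_reverse`, `n_other`, and percentages `pct_direct`,
#'   `pct_reverse`.
#' @export
assay_efficiency <- function(records, n_arrays_scored) {
  if (n_arrays_scored <= 0L) stop("n_arrays_scored must be positive")
  ol <- records[records$source == "oligo", , drop = FALSE]
  n_direct <- sum(ol$processing == "properly_processed_direct")
  n_reverse <- sum(ol$processing == "properly_processed_reverse")
  n_other <- nrow(ol) - n_direct - n_reverse
  structure(list(n_arrays_scored = as.integer(n_arrays_scored),
                 n_direct = n_direct, n_reverse = n_reverse,
                 n_other = n_other,
                 pct_direct = 100 * n_direct / n_arrays_scored,
                 pct_reverse = 100 * n_reverse / n_arrays_scored),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf(
    "assay_result: %d arrays scored; direct %.2f%% (%d), reverse %.2f%% (%d), other %d\n",
    x$n_arrays_scored, x$pct_direct, x$n_direct, x$pct_reverse,
    x$n_reverse, x$n_other))
  invisible(x)
}
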