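#' Find CRISPR repeat sites in a read
#'
#' Greedy left-to-right scan for non-overlapping occurrences of the repeat
#' with at most `max_mm` mismatches; N in the (quality-masked) read matches
#' any base.
#'
#' @param read a single read sequence (masked).
#' @param repeat_seq the repeat.
#' @param max_mm mismatch tolerance (default 2).
#' @return integer vector of 0-based start positions.
#' @export
find_repeat_sites <- function(read, repeat_seq, max_mm = 2L) {
  if (nchar(read) < nchar(repeat_seq)) return(integer())
  m <- matchPattern(DNAString(repeat_seq), DNAString(read),
                    max.mismatch = max_mm, fixed = "pattern")
  st <- sort(start(m)) - 1L
  rlen <- nchar(repeat_seq)
  keep <- integer()
  last_end <- -1L
  for (p in st) {
    if (p >= last_end) { keep <- c(keep, p); last_end <- p + rlen }
  }
  keep
}

#' Extract inter-repeat spacers from an array read
#'
#' Reads containing two or more repeat sites yield the substrings between
#' consecutive repeats, leader-proximal first; reads with fewer than two
#' sites yield nothing.
#'
#' @param read a single read sequence (masked).
#' @param repeat_seq the repeat.
#' @param max_mm mismatch tolerance for repeat matching.
#' @return character vector of spacer sequences (possibly empty).
#' @export
extract_spacers <- function(read, repeat_seq, max_mm = 2L) {
  sites <- find_repeat_sites(read, repeat_seq, max_mm)
  if (length(sites) < 2L) return(character())
  rlen <- nchar(repeat_seq)
  out <- character()
  for (k in seq_len(length(sites) - 1L)) {
    s <- sites[k] + rlen
    e <- sites[k + 1L]
    if (e > s) out <- c(out, substr(read, s + 1L, e))
  }
  out
}

#' Map extracted spacers to the genome
#'
#' Only spacers of exactly the preset spacer length proceed (others are
#' flagged `wrong_length`); mapping is exact (0 mismatches; N never
#' matches) on both strands. Spacers aligning to a single position are
#' accepted; several positions give `multi_hit`, none gives `unmapped`.
#' For mapped records the consensus-PAM status is recorded.
#'
#' @param spacers character vector of spacer sequences (one row per
#'   extracted spacer instance; duplicates allowed).
#' @param genome a [genome_ref()].
#' @param preset a [system_preset()].
#' @return data.frame of spacer records: `seq`, `status` ("mapped",
#'   "unmapped", "wrong_length", "multi_hit"), `start`, `end`, `strand`
#'   (NA unless mapped), `pam_ok`, and logical flag columns `slippage`,
#'   `flippage` (initialised FALSE; see [filter_slippage_flippage()]).
#' @export
map_spacers <- function(spacers, genome, preset) {
  n <- length(spacers)
  out <- data.frame(seq = spacers, status = "unmapped",
                    contig = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, pam_ok = FALSE,
                    slippage = FALSE, flippage = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  wrong <- nchar(spacers) != preset$spacer_len
  out$status[wrong] <- "wrong_length"
  uniq <- unique(spacers[!wrong])
  res <- lapply(uniq, function(sp) {
    if (grepl("N", sp, fixed = TRUE)) return(list(status = "unmapped"))
    align_unique(sp, genome, kmax = 0L, length_filter = FALSE)
  })
  names(res) <- uniq
  for (i in which(!wrong)) {
    h <- res[[spacers[i]]]
    if (h$status == "unique") {
      out$status[i] <- "mapped"
      out$contig[i] <- h$contig
      out$start[i] <- h$start; out$end[i] <- h$end; out$strand[i] <- h$strand
    } else if (h$status == "ambiguous") {
      out$status[i] <- "multi_hit"
    }
  }
  mp <- out$status == "mapped"
  for (ctg in unique(out$contig[mp])) {
    sel <- mp & out$contig == ctg
    out$pam_ok[sel] <- has_consensus_pam_many(genome, ctg, out$start[sel],
                                              out$end[sel], out$strand[sel],
                                              preset)
  }
  out
}

#' Flag slippage and flippage acquisition artifacts
#'
#' The canonical set is the mapped records carrying the consensus PAM. A
#' mapped non-canonical record is flagged `slippage` if its interval is
#' shifted by `slip_window` (1-5 nt by default) from a canonical interval
#' on the same strand, and `flippage` if it reverse-complements onto a
#' canonical interval with at least `flip_overlap` fractional overlap.
#' These windows are this package's operationalisation of the filter;
#' flagged records are excluded from downstream statistics.
#'
#' @param records spacer records from [map_spacers()].
#' @param slip_window maximum canonical-to-record shift (nt).
#' @param flip_overlap minimum fractional overlap for flippage.
#' @return the records with `slippage`/`flippage` flags set.
#' @export
filter_slippage_flippage <- function(records, slip_window = 5L,
                                     flip_overlap = 0.9) {
  mp <- records$status == "mapped"
  canon <- records[mp & records$pam_ok, , drop = FALSE]
  if (nrow(canon) == 0L) return(records)
  cs <- canon[!duplicated(paste(canon$start, canon$end, canon$strand)), ]
  for (i in which(mp & !records$pam_ok)) {
    same <- cs$strand == records$strand[i]
    sh <- abs(cs$start - records$start[i])
    if (any(same & sh >= 1L & sh <= slip_window)) {
      records$slippage[i] <- TRUE
      next
    }
    opp <- cs$strand != records$strand[i]
    ov <- pmax(0L, pmin(cs$end, records$end[i]) -
                 pmax(cs$start, records$start[i]))
    len <- records$end[i] - records$start[i]
    if (any(opp & ov / len >= flip_overlap)) records$flippage[i] <- TRUE
  }
  records
}

#' Spacer acquisition statistics
#'
#' Over retained records (mapped, unflagged), reports the consensus-PAM
#' fraction, the orientation class split (SpNT iff the protospacer strand
#' equals the PPS nontarget strand), the side split relative to the PPS
#' PAM, and per-bin percentage vectors by class (percent of all retained
#' spacers; the class vectors jointly sum to 100).
#'
#' @param records spacer records after [filter_slippage_flippage()].
#' @param pps_obj a [pps()].
#' @param preset a [system_preset()].
#' @param genome_len contig length (for binning).
#' @param bin bin width in nt (default 1000).
#' @return a list with `n_retained`, `pam_fraction`, `by_class` (counts),
#'   `by_side` (counts), `per_kb` (data.frame `bin_start`, `pct_SpNT`,
#'   `pct_SpT`), and `accounting` (status/flag counts).
#' @export
spacer_stats <- function(records, pps_obj, preset, genome_len,
                         bin = 1000L) {
  acct <- c(extracted = nrow(records),
            mapped = sum(records$status == "mapped"),
            unmapped = sum(records$status == "unmapped"),
            wrong_length = sum(records$status == "wrong_length"),
            multi_hit = sum(records$status == "multi_hit"),
            slippage = sum(records$slippage),
            flippage = sum(records$flippage))
  keep <- records$status == "mapped" & !records$slippage & !records$flippage
  ret <- records[keep, , drop = FALSE]
  nbin <- ceiling(genome_len / bin)
  per_kb <- data.frame(bin_start = (seq_len(nbin) - 1L) * bin,
                       pct_SpNT = 0, pct_SpT = 0)
  if (nrow(ret) == 0L)
    return(list(n_retained = 0L, pam_fraction = NA_real_,
                by_class = c(SpNT = 0L, SpT = 0L),
                by_side = c(upstream = 0L, downstream = 0L),
                per_kb = per_kb, accounting = acct))
  nt <- pps_obj$protospacer$strand
  klass <- ifelse(ret$strand == nt, "SpNT", "SpT")
  ps <- pps_obj$protospacer
  pam_left <- pps_obj$pam_interval$start < ps$start
  mid <- (ret$start + ret$end) / 2
  side <- ifelse((mid < (ps$start + ps$end) / 2) == pam_left,
                 "upstream", "downstream")
  bins <- pmin(nbin, ret$start %/% bin + 1L)
  for (kl in c("SpNT", "SpT")) {
    cnt <- tapply(rep(1L, sum(klass == kl)), bins[klass == kl], sum)
    col <- paste0("pct_", kl)
    per_kb[[col]][as.integer(names(cnt))] <- 100 * as.numeric(cnt) / nrow(ret)
  }
  list(n_retained = nrow(ret),
       pam_fraction = mean(ret$pam_ok),
       by_class = c(SpNT = sum(klass == "SpNT"), SpT = sum(klass == "SpT")),
       by_side = c(upstream = sum(side == "upstream"),
                   downstream = sum(side == "downstream")),
       per_kb = per_kb, accounting = acct)
}
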