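#' Classify fragments by strand role and side relative to the PPS
#'
#' A fragment's strand role is NT (nontarget) iff its strand equals the PPS
#' protospacer strand (the strand whose sequence matches the targeting
#' crRNA spacer, i.e. the displaced strand), and T otherwise. Its side is
#' `upstream` iff it lies on the PAM-proximal side of the PPS. Fragments
#' overlapping the PPS are classified by midpoint and flagged.
#'
#' @param tab a fragment table ([build_fragment_table()]).
#' @param pps_obj a [pps()].
#' @param preset a [system_preset()] (unused by the rule itself; retained
#'   for interface symmetry).
#' @return the table with added columns `strand_role` ("NT"/"T"), `side`
#'   ("upstream"/"downstream") and `pps_overlap` (logical flag).
#' @export
classify_fragments <- function(tab, pps_obj, preset = NULL) {
  ps <- pps_obj$protospacer
  pam_left <- pps_obj$pam_interval$start < ps$start
  out <- tab
  out$strand_role <- ifelse(tab$strand == ps$strand, "NT", "T")
  on_left <- tab$end <= ps$start
  on_right <- tab$start >= ps$end
  overlap <- !on_left & !on_right
  mid <- (tab$start + tab$end) / 2
  left <- on_left | (overlap & mid < (ps$start + ps$end) / 2)
  out$side <- ifelse(left == pam_left, "upstream", "downstream")
  out$pps_overlap <- overlap
  out
}

#' Abundance-weighted fragment length distribution
#'
#' Computes the abundance-weighted histogram of insert lengths, optionally
#' restricted to a strand role and/or side (requires a classified table).
#' With several replicate tables, the per-length mean and SEM across
#' replicates are returned.
#'
#' @param tabs a fragment table or a list of replicate fragment tables.
#' @param strand_role optional filter ("NT"/"T").
#' @param side optional filter ("upstream"/"downstream").
#' @return data.frame (`length`, `mean`, `sem`); `sem` is NA for a single
#'   table and 0 for identical replicates.
#' @export
length_distribution <- function(tabs, strand_role = NULL, side = NULL) {
  if (is.data.frame(tabs)) tabs <- list(tabs)
  hists <- lapply(tabs, function(tb) {
    if (!is.null(strand_role)) tb <- tb[tb$strand_role %in% strand_role, ]
    if (!is.null(side)) tb <- tb[tb$side %in% side, ]
    if (nrow(tb) == 0L) return(numeric())
    tapply(tb$abundance, tb$length, sum)
  })
  lens <- sort(unique(as.integer(unlist(lapply(hists, names)))))
  if (length(lens) == 0L)
    return(data.frame(length = integer(), mean = numeric(), sem = numeric()))
  m <- vapply(hists, function(h) {
    v <- stats::setNames(numeric(length(lens)), lens)
    v[names(h)] <- h
    v
  }, numeric(length(lens)))
  m <- matrix(m, nrow = length(lens))
  data.frame(length = lens,
             mean = rowMeans(m),
             sem = if (ncol(m) > 1L)
               apply(m, 1L, stats::sd) / sqrt(ncol(m)) else NA_real_)
}

#' End-anchored position frequency matrix
#'
#' Stacks, abundance-weighted, the genomic sequence on each fragment's own
#' strand over a window of offsets around its anchored end (5' or 3').
#' Offset 0 is the terminal fragment base; negative offsets run in the
#' fragment's 5' direction and positive offsets in its 3' direction, so the
#' default 5' window (-10, +15) spans 26 columns. Windows falling off the
#' contig are skipped and counted; N bases are not counted.
#'
#' @param tab fragment table.
#' @param genome a [genome_ref()].
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param length_range integer length-2 vector; only fragments with
#'   `length` in this inclusive range contribute.
#' @param window inclusive offset range, e.g. `c(-10, 15)`.
#' @return an object of class `"pfm"`: list with `counts` (4 x width
#'   matrix, rows A/C/G/T, columns named by offset), `n` (total fragment
#'   abundance stacked), `n_skipped`, `window`, `anchor`.
#' @export
end_pfm <- function(tab, genome, anchor = c("five_prime", "three_prime"),
                    length_range, window) {
  anchor <- match.arg(anchor)
  w1 <- as.integer(window[1L]); w2 <- as.integer(window[2L])
  width <- w2 - w1 + 1L
  tb <- tab[tab$length >= length_range[1L] & tab$length <= length_range[2L], ,
            drop = FALSE]
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), as.character(w1:w2)))
  n <- 0; n_skipped <- 0
  if (nrow(tb)) {
    plus <- tb$strand == "+"
    apos <- if (anchor == "five_prime") ifelse(plus, tb$start, tb$end - 1L)
            else ifelse(plus, tb$end - 1L, tb$start)
    top_start <- ifelse(plus, apos + w1, apos - w2)
    top_end <- ifelse(plus, apos + w2 + 1L, apos - w1 + 1L)
    seqs <- extract_seq_many(genome, tb$contig[1L], as.integer(top_start),
                             as.integer(top_end), tb$strand)
    for (i in seq_len(nrow(tb))) {
      if (is.na(seqs[i])) { n_skipped <- n_skipped + tb$abundance[i]; next }
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      keep <- ch %in% c("A", "C", "G", "T")
      if (any(keep)) {
        idx <- cbind(match(ch[keep], c("A", "C", "G", "T")), which(keep))
        counts[idx] <- counts[idx] + tb$abundance[i]
      }
      n <- n + tb$abundance[i]
    }
  }
  structure(list(counts = counts, n = n, n_skipped = n_skipped,
                 window = c(w1, w2), anchor = anchor), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm: %s anchor, window (%d,%d), n = %g (skipped %g)\n",
              x$anchor, x$window[1L], x$window[2L], x$n, x$n_skipped))
  invisible(x)
}

#' Column frequencies of a PFM
#'
#' @param pfm a [end_pfm()] object.
#' @return 4 x width matrix of per-column base frequencies (columns with no
#'   counts are NA).
#' @export
pfm_freq <- function(pfm) {
  cs <- colSums(pfm$counts)
  f <- sweep(pfm$counts, 2L, cs, "/")
  f[, cs == 0] <- NA_real_
  f
}

#' Call a consensus motif from an end-anchored PFM
#'
#' Computes per-column information content (2 + sum f log2 f, uniform
#' background) and reports every contiguous run of columns above
#' `ic_threshold` with its majority-base consensus.
#'
#' @param pfm a [end_pfm()] object with `n >= 20`.
#' @param ic_threshold information-content threshold in bits (default 1.0).
#' @return list with `ic` (named numeric vector by offset) and `motifs`
#'   (data.frame `offset_start`, `offset_end`, `motif`); zero rows if no
#'   column passes.
#' @export
call_pam <- function(pfm, ic_threshold = 1.0) {
  if (pfm$n < 20) stop("insufficient data: pfm built from n = ", pfm$n,
                       " fragments (need >= 20)")
  f <- pfm_freq(pfm)
  ic <- apply(f, 2L, function(col) {
    if (anyNA(col)) return(NA_real_)
    col <- col[col > 0]
    2 + sum(col * log2(col))
  })
  above <- !is.na(ic) & ic > ic_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  offs <- as.integer(colnames(f))
  motifs <- do.call(rbind, lapply(sel, function(k) {
    cols <- starts[k]:ends[k]
    motif <- paste(rownames(f)[apply(f[, cols, drop = FALSE], 2L,
                                     which.max)], collapse = "")
    data.frame(offset_start = offs[starts[k]], offset_end = offs[ends[k]],
               motif = motif, stringsAsFactors = FALSE)
  }))
  if (is.null(motifs))
    motifs <- data.frame(offset_start = integer(), offset_end = integer(),
                         motif = character(), stringsAsFactors = FALSE)
  list(ic = stats::setNames(ic, colnames(f)), motifs = motifs)
}

#' Pair complementary fragments into duplex calls
#'
#' Reconstructs double-stranded prespacers from the single-stranded
#' fragment table. A call is emitted for a plus-strand fragment
#' `A = [a1, a2)` and minus-strand fragment `B = [b1, b2)` iff the pair
#' shares one blunt end and the longer strand protrudes at its 3' terminus:
#' `a2 == b2` with `b1 < a1` (blunt right end, 3' overhang `a1 - b1` on the
#' left) or `a1 == b1` with `a2 > b2` (blunt left end, 3' overhang
#' `a2 - b2` on the right). The overhang side is the PAM side. End matching
#' is exact by default (`tol = 0`); consensus calling upstream is expected
#' to absorb sequencing errors.
#'
#' @param tab fragment table.
#' @param genome a [genome_ref()].
#' @param preset a [system_preset()] (sets the protospacer length reported
#'   per call).
#' @param tol blunt-end matching tolerance in nt (default 0).
#' @return data.frame of class `"duplex_calls"`: `contig`, `duplex_start`,
#'   `duplex_end` (the paired footprint = the short strand), `overhang`,
#'   `pam_side`, `pam_seq` (3 bases spanning the cut at the overhang side,
#'   on the short strand's strand), `short_len`, `long_len`,
#'   `support_short`, `support_long`, and the implied protospacer
#'   (`ps_start`, `ps_end`, `ps_strand`). Fragments in no call are listed
#'   in the `"unpaired"` attribute.
#' @export
pair_duplexes <- function(tab, genome, preset, tol = 0L) {
  A <- tab[tab$strand == "+", , drop = FALSE]
  B <- tab[tab$strand == "-", , drop = FALSE]
  calls <- NULL
  used <- rep(FALSE, nrow(tab))
  idxA <- which(tab$strand == "+"); idxB <- which(tab$strand == "-")
  if (nrow(A) && nrow(B)) {
    right_blunt <- abs(outer(A$end, B$end, "-")) <= tol &
      outer(A$start, B$start, "-") > 0
    left_blunt <- abs(outer(A$start, B$start, "-")) <= tol &
      outer(A$end, B$end, "-") > 0
    mk <- function(ij, side) {
      i <- ij[, 1L]; j <- ij[, 2L]
      if (side == "left") {                     # blunt right, overhang left
        d1 <- A$start[i]; d2 <- A$end[i]
        overhang <- A$start[i] - B$start[j]
        short_len <- A$length[i]; long_len <- B$length[j]
        s_short <- A$abundance[i]; s_long <- B$abundance[j]
      } else {                                  # blunt left, overhang right
        d1 <- B$start[j]; d2 <- B$end[j]
        overhang <- A$end[i] - B$end[j]
        short_len <- B$length[j]; long_len <- A$length[i]
        s_short <- B$abundance[j]; s_long <- A$abundance[i]
      }
      data.frame(contig = A$contig[i], duplex_start = d1, duplex_end = d2,
                 overhang = overhang, pam_side = side,
                 short_len = short_len, long_len = long_len,
                 support_short = s_short, support_long = s_long,
                 i = i, j = j, stringsAsFactors = FALSE)
    }
    res <- list()
    if (any(right_blunt)) res <- c(res, list(mk(which(right_blunt,
                                                      arr.ind = TRUE), "left")))
    if (any(left_blunt)) res <- c(res, list(mk(which(left_blunt,
                                                     arr.ind = TRUE), "right")))
    if (length(res)) {
      calls <- do.call(rbind, res)
      used[idxA[unique(calls$i)]] <- TRUE
      used[idxB[unique(calls$j)]] <- TRUE
    }
  }
  if (is.null(calls)) {
    calls <- data.frame(contig = character(), duplex_start = integer(),
                        duplex_end = integer(), overhang = integer(),
                        pam_side = character(), short_len = integer(),
                        long_len = integer(), support_short = integer(),
                        support_long = integer(), stringsAsFactors = FALSE)
    calls$pam_seq <- character()
    calls$ps_start <- integer(); calls$ps_end <- integer()
    calls$ps_strand <- character()
  } else {
    calls$i <- NULL; calls$j <- NULL
    left <- calls$pam_side == "left"
    calls$pam_seq <- ifelse(left,
      extract_seq_many(genome, calls$contig[1L], calls$duplex_start - 2L,
                       calls$duplex_start + 1L, rep("+", nrow(calls))),
      extract_seq_many(genome, calls$contig[1L], calls$duplex_end - 1L,
                       calls$duplex_end + 2L, rep("-", nrow(calls))))
    L <- preset$spacer_len
    calls$ps_start <- ifelse(left, calls$duplex_end - L, calls$duplex_start)
    calls$ps_end <- calls$ps_start + L
    calls$ps_strand <- ifelse(left, "+", "-")
    row.names(calls) <- NULL
  }
  class(calls) <- c("duplex_calls", "data.frame")
  attr(calls, "unpaired") <- tab[!used, , drop = FALSE]
  calls
}

#' Correlation between complementary strand abundances
#'
#' Pearson correlation between the short-strand and long-strand supports
#' across duplex calls; a positive value indicates that the two strands of
#' each prespacer derive from common double-stranded molecules.
#'
#' @param calls a [pair_duplexes()] table with at least 3 rows.
#' @return Pearson r in [-1, 1].
#' @export
complementary_abundance_correlation <- function(calls) {
  if (nrow(calls) < 3L)
    stop("undefined correlation: need >= 3 duplex calls, got ", nrow(calls))
  x <- calls$support_short; y <- calls$support_long
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in supports")
  stats::cor(x, y)
}

#' Correlation between fragment and acquired-spacer abundances
#'
#' Joins duplex calls to mapped spacer records on the identical protospacer
#' interval and strand, then computes the Pearson correlation between total
#' duplex support and spacer counts.
#'
#' @param calls a [pair_duplexes()] table.
#' @param records mapped spacer records ([map_spacers()]), retained rows.
#' @return Pearson r, with attributes `n_joined`, `n_calls`,
#'   `n_spacer_sites`; empty join is an error.
#' @export
fragment_spacer_correlation <- function(calls, records) {
  rec <- records[records$status == "mapped", , drop = FALSE]
  sp_key <- paste(rec$start, rec$end, rec$strand, sep = "|")
  sp_cnt <- tapply(rep(1L, length(sp_key)), sp_key, sum)
  call_key <- paste(calls$ps_start, calls$ps_end, calls$ps_strand, sep = "|")
  support <- tapply(calls$support_short + calls$support_long, call_key, sum)
  common <- intersect(names(sp_cnt), names(support))
  if (length(common) == 0L)
    stop("undefined correlation: no protospacers shared between duplex",
         " calls and spacer records")
  if (length(common) < 3L)
    stop("undefined correlation: only ", length(common), " shared sites")
  r <- stats::cor(as.numeric(support[common]), as.numeric(sp_cnt[common]))
  attr(r, "n_joined") <- length(common)
  attr(r, "n_calls") <- length(support)
  attr(r, "n_spacer_sites") <- length(sp_cnt)
  r
}
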