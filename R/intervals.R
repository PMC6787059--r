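#' Genomic interval
#'
#' A lightweight 0-based, half-open interval on a named contig. The 5'
#' terminus of a `+` feature is at `start`; the 5' terminus of a `-` feature
#' is at `end - 1` (top-strand coordinates throughout).
#'
#' @param contig contig name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return a list of class `"fs_interval"`.
#' @export
interval <- function(contig, start, end, strand = "+") {
  stopifnot(length(contig) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "fs_interval")
}

#' @export
print.fs_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)%s\n", x$contig, x$start, x$end, x$strand))
  invisible(x)
}

iv_width <- function(iv) iv$end - iv$start

#' Reference genome
#'
#' Wraps one or more named contig sequences. Construct from a named
#' character vector or read from FASTA with [read_genome()].
#'
#' @param seqs named character vector of contig sequences (A/C/G/T/N).
#' @return a list of class `"genome_ref"`.
#' @export
genome_ref <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("contigs must be named")
  seqs <- vapply(seqs, toupper, "")
  check_dna(seqs)
  structure(list(seqs = seqs), class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("genome_ref with", length(x$seqs), "contig(s):",
      paste(sprintf("%s (%d nt)", names(x$seqs), nchar(x$seqs)), collapse = ", "),
      "\n")
  invisible(x)
}

contig_seq <- function(genome, contig) {
  s <- genome$seqs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  s
}

#' Read / write a reference genome as FASTA
#'
#' @param path FASTA file path.
#' @return for `read_genome`, a [genome_ref()].
#' @export
read_genome <- function(path) {
  ss <- readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_ref(stats::setNames(as.character(ss), nm))
}

#' @param genome a [genome_ref()].
#' @rdname read_genome
#' @export
write_genome <- function(genome, path) {
  ss <- DNAStringSet(genome$seqs)
  writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract the sequence of an interval
#'
#' Returns the top-strand substring for `+` intervals and its reverse
#' complement for `-` intervals, i.e. the sequence read 5' to 3' along the
#' feature's own strand.
#'
#' @param genome a [genome_ref()].
#' @param iv an [interval()].
#' @return a character string of length `end - start`.
#' @export
extract_seq <- function(genome, iv) {
  s <- contig_seq(genome, iv$contig)
  if (iv$end > nchar(s)) stop("interval out of range: end ", iv$end,
                              " > contig length ", nchar(s))
  sub <- substr(s, iv$start + 1L, iv$end)
  if (iv$strand == "-") revcomp(sub) else sub
}

# Vectorised top-strand substring extraction (0-based half-open starts/ends),
# with revcomp applied where strand == "-". Out-of-range rows return NA.
extract_seq_many <- function(genome, contig, start, end, strand) {
  s <- contig_seq(genome, contig)
  ok <- start >= 0L & end <= nchar(s) & start < end
  out <- rep(NA_character_, length(start))
  if (any(ok)) out[ok] <- substring(s, start[ok] + 1L, end[ok])
  neg <- ok & strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  out
}
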