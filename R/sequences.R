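#' @importFrom Biostrings DNAString DNAStringSet reverseComplement matchPattern
#'   vmatchPattern writeXStringSet readDNAStringSet BStringSet neditStartingAt
#' @importFrom IRanges IRanges start end width
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate a nucleotide sequence
#'
#' Checks that a character vector contains only sequences over the
#' \{A, C, G, T, N\} alphabet and stops with an informative error otherwise.
#'
#' @param x character vector of sequences.
#' @return `x`, invisibly, if valid.
#' @export
check_dna <- function(x) {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid nucleotide symbol in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "),
         " (alphabet is A/C/G/T/N)")
  }
  invisible(x)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of one or more sequences; `N` maps to `N`.
#' An involution: `revcomp(revcomp(x)) == x`.
#'
#' @param x character vector of sequences over \{A,C,G,T,N\}.
#' @return character vector of the same length.
#' @examples
#' revcomp("GCCCAATTTACTACTCGTTCTGGTGTTTCTCGT")
#' @export
revcomp <- function(x) {
  check_dna(x)
  out <- as.character(reverseComplement(DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Generate a random DNA sequence at a given GC content
#'
#' Draws bases independently with P(G) = P(C) = gc/2. Uses the current RNG
#' state; seed management is left to the caller.
#'
#' @param n sequence length in nt.
#' @param gc GC fraction in [0, 1].
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Hamming distance between equal-length strings; if n_wild, N matches any base.
hamming <- function(a, b, n_wild = FALSE) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  d <- av != bv
  if (n_wild) d <- d & av != "N" & bv != "N"
  sum(d)
}
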