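#' FASTQ input and output
#'
#' Reads are held in memory as a data.frame with columns `id`, `seq`
#' (A/C/G/T/N) and `qual` (Phred+33 encoded string of the same length).
#' I/O goes through Biostrings.
#'
#' @param path FASTQ file path (4-line records, Phred+33).
#' @return for `read_fastq`, a read data.frame.
#' @export
read_fastq <- function(path) {
  ss <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(ss),
             seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @param reads a read data.frame (`id`, `seq`, `qual`).
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  ss <- DNAStringSet(reads$seq)
  names(ss) <- reads$id
  writeXStringSet(ss, path, format = "fastq",
                  qualities = BStringSet(reads$qual))
  invisible(path)
}

# Phred+33 helpers.
phred_to_int <- function(qual) lapply(qual, function(q) utf8ToInt(q) - 33L)
int_to_phred <- function(q) vapply(q, function(v) intToUtf8(v + 33L), "")
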