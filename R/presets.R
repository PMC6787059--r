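#' CRISPR system presets
#'
#' Bundles the structural parameters of a type I adaptation system: spacer
#' length, the distribution of prespacer duplex lengths, the 3'-overhang
#' rule, the PAM, and the orientation mode that dictates which genomic
#' strand supplies protospacers upstream versus downstream of the priming
#' protospacer (PPS).
#'
#' For the I-E preset the PAM is 5'-AAG-3' with the G being the first
#' protospacer base (prespacers are cut between AA and G), duplexes are 33
#' or 34 bp with a 4- or 3-nt 3' overhang so that the long strand always
#' spans 37 nt. For the I-F preset the defaults (32-nt spacer, GG PAM fully
#' outside the protospacer, 5-nt overhang, reversed orientation bias) are
#' literature-informed configuration defaults and can be overridden.
#'
#' @param name `"IE"` or `"IF"`.
#' @param ... overrides for any preset field (e.g. `pam = "GG"`).
#' @return a list of class `"system_preset"` with fields `name`,
#'   `spacer_len`, `duplex_len_choices` (data.frame `len`, `prob`),
#'   `overhang_for` (named vector duplex length -> overhang), `long_len`,
#'   `pam`, `pam_inside` (number of PAM bases inside the protospacer),
#'   `pam_side`, `orientation_mode`, `logo_window_5p`, `logo_window_3p`.
#' @export
system_preset <- function(name = c("IE", "IF"), ...) {
  name <- match.arg(name)
  p <- if (name == "IE") {
    list(
      name = "IE",
      spacer_len = 33L,
      duplex_len_choices = data.frame(len = c(33L, 34L), prob = c(0.7, 0.3)),
      long_len = 37L,
      pam = "AAG",
      pam_inside = 1L,           # the G is protospacer position 1
      pam_side = "five_prime",
      orientation_mode = "IE",   # upstream sites on the nontarget strand
      logo_window_5p = c(-10L, 15L),
      logo_window_3p = c(-20L, 5L)
    )
  } else {
    list(
      name = "IF",
      spacer_len = 32L,
      duplex_len_choices = data.frame(len = 32L, prob = 1),
      long_len = 37L,
      pam = "GG",
      pam_inside = 0L,           # GG fully 5' of the protospacer
      pam_side = "five_prime",
      orientation_mode = "IF",   # orientation bias reversed vs I-E
      logo_window_5p = c(-10L, 15L),
      logo_window_3p = c(-20L, 5L)
    )
  }
  ov <- list(...)
  for (k in names(ov)) {
    if (!k %in% names(p)) stop("unknown preset field: ", k)
    p[[k]] <- ov[[k]]
  }
  if (abs(sum(p$duplex_len_choices$prob) - 1) > 1e-9)
    stop("duplex_len_choices probabilities must sum to 1")
  oh <- p$long_len - p$duplex_len_choices$len
  if (any(oh <= 0))
    stop("every duplex length must be shorter than the long strand (",
         p$long_len, " nt)")
  p$overhang_for <- stats::setNames(as.integer(oh),
                                    as.character(p$duplex_len_choices$len))
  structure(p, class = "system_preset")
}

#' @export
print.system_preset <- function(x, ...) {
  cat(sprintf("system_preset %s: spacer %d nt, duplex %s bp, long strand %d nt, PAM %s\n",
              x$name, x$spacer_len,
              paste(x$duplex_len_choices$len, collapse = "/"),
              x$long_len, x$pam))
  invisible(x)
}

#' CRISPR locus description
#'
#' @param leader leader sequence (new spacers are inserted at the
#'   leader-repeat junction).
#' @param repeat_seq repeat sequence (>= 8 nt).
#' @param spacers character vector of preexisting spacers, leader-proximal
#'   first; each must have length `preset$spacer_len`.
#' @param preset a [system_preset()].
#' @return a list of class `"crispr_locus"`.
#' @export
crispr_locus <- function(leader, repeat_seq, spacers, preset) {
  check_dna(c(leader, repeat_seq, spacers))
  if (nchar(repeat_seq) < 8L) stop("repeat must be >= 8 nt")
  if (any(nchar(spacers) != preset$spacer_len))
    stop("all spacers must have length ", preset$spacer_len)
  structure(list(leader = leader, repeat_seq = repeat_seq,
                 spacers = as.character(spacers)),
            class = "crispr_locus")
}

#' Priming protospacer (PPS)
#'
#' The protospacer targeted by the resident crRNA. The `protospacer`
#' interval's strand is the nontarget strand, i.e. the strand whose
#' sequence matches the targeting spacer; the target strand is the one
#' base-paired by the crRNA.
#'
#' @param protospacer [interval()] of the protospacer (nontarget strand).
#' @param pam_interval [interval()] of the PAM on the same strand.
#' @return a list of class `"pps"`.
#' @export
pps <- function(protospacer, pam_interval) {
  structure(list(protospacer = protospacer, pam_interval = pam_interval),
            class = "pps")
}

# PAM interval (same strand) for a protospacer interval under a preset:
# the PAM lies 5' of the protospacer with `pam_inside` bases inside it.
pam_interval_for <- function(protospacer, preset) {
  m <- nchar(preset$pam)
  n_out <- m - preset$pam_inside
  if (protospacer$strand == "+") {
    interval(protospacer$contig, protospacer$start - n_out,
             protospacer$start - n_out + m, "+")
  } else {
    interval(protospacer$contig, protospacer$end + n_out - m,
             protospacer$end + n_out, "-")
  }
}

#' Test a protospacer for the consensus PAM
#'
#' For the I-E preset this is TRUE iff, on the protospacer's own strand, the
#' first protospacer base is G and the two bases immediately 5' of it are
#' A, A (the 5'-AAG-3' PAM with its G inside the protospacer). Other presets
#' apply the analogous rule given by their `pam` / `pam_inside` fields. An N
#' at any PAM position never satisfies the consensus.
#'
#' @param genome a [genome_ref()].
#' @param protospacer an [interval()] with length `preset$spacer_len`.
#' @param preset a [system_preset()].
#' @return TRUE or FALSE; flanks falling off the contig are a bounds error.
#' @export
has_consensus_pam <- function(genome, protospacer, preset) {
  if (iv_width(protospacer) != preset$spacer_len)
    stop("protospacer length ", iv_width(protospacer),
         " != preset spacer length ", preset$spacer_len)
  pam_iv <- pam_interval_for(protospacer, preset)
  if (pam_iv$start < 0L) stop("PAM flank off contig start")
  identical(extract_seq(genome, pam_iv), preset$pam)
}

#' Vectorised consensus-PAM check
#'
#' Same rule as [has_consensus_pam()] over coordinate vectors; off-contig
#' flanks yield FALSE instead of an error.
#'
#' @param genome a [genome_ref()].
#' @param contig contig name.
#' @param start,end,strand protospacer coordinate vectors.
#' @param preset a [system_preset()].
#' @return logical vector.
#' @export
has_consensus_pam_many <- function(genome, contig, start, end, strand, preset) {
  m <- nchar(preset$pam)
  n_out <- m - preset$pam_inside
  ps <- ifelse(strand == "+", start - n_out, end + n_out - m)
  pe <- ps + m
  seqs <- extract_seq_many(genome, contig, as.integer(ps), as.integer(pe), strand)
  !is.na(seqs) & seqs == preset$pam
}
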