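#' Simulation configuration
#'
#' Parameters of the synthetic self-targeting system: the genome, the
#' priming protospacer (PPS), the protospacer-selection model (consensus-PAM
#' sites whose usage decays exponentially with distance from the PPS, with
#' lognormal per-site dispersion), the prespacer structural model given by
#' the preset, and the sequencing library model (adapter/UMI layout, PCR
#' overamplification, substitution errors, quality profile).
#'
#' All stochastic stages draw from R's global RNG; each simulation entry
#' point seeds it deterministically from `seed` (with a small fixed offset
#' per stage) so that stages are reproducible both in isolation and chained.
#'
#' @param genome_len genome length in nt.
#' @param gc genome GC fraction.
#' @param seed integer seed for all randomness.
#' @param preset a [system_preset()].
#' @param pps_pos 0-based position of the PPS protospacer start; must leave
#'   at least 10 kb of genome on each side.
#' @param locus_pos position at which the CRISPR locus is embedded (outside
#'   the protospacer sampling window around the PPS).
#' @param n_sites number of protospacer sites selected on each side of the
#'   PPS.
#' @param site_window maximum distance (nt) from the PPS at which sites are
#'   sampled.
#' @param decay_lambda exponential length scale (nt) of site-usage decay
#'   with distance from the PPS.
#' @param site_weight_sigma sdlog of the lognormal per-site usage factor.
#' @param n_duplexes total number of prespacer duplex molecules.
#' @param pcr_dup_p geometric parameter of PCR overamplification; each
#'   molecule yields `1 + Geometric(1 - pcr_dup_p)` reads (mean
#'   `1/(1 - pcr_dup_p)`).
#' @param err_rate per-base substitution error probability.
#' @param lowq_rate per-base probability of a quality score below 20.
#' @param extension_fraction fraction of CRISPR arrays carrying a newly
#'   acquired spacer.
#' @param slip_rate,flip_rate per-acquisition probabilities of a slippage
#'   (1-3 nt shifted) or flippage (reverse-complemented) artifact.
#' @param background_rate fraction of sequenced molecules that are
#'   unstructured degradation fragments (20-60 nt) rather than prespacer
#'   strands.
#' @param read_len instrument read length; reads shorter than this are
#'   padded with random sequence past the 3' adapter, longer layouts are
#'   truncated.
#' @param n_arrays number of array amplicon reads to simulate.
#' @param strict_pam if TRUE (default), every selected protospacer site
#'   carries the consensus PAM.
#' @param barcodes 5'-adapter barcode set (internal controls).
#' @param umi_len UMI length on each adapter.
#' @param anchor fixed 3'-adapter anchor sequence.
#' @param leader_len leader length of the synthetic locus.
#' @param repeat_seq repeat sequence of the synthetic locus.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(genome_len = 100000L, gc = 0.5, seed = 1L,
                       preset = system_preset("IE"),
                       pps_pos = 60000L, locus_pos = 2000L,
                       n_sites = 40L, site_window = 25000L,
                       decay_lambda = 5000, site_weight_sigma = 1,
                       n_duplexes = 2000L, pcr_dup_p = 0.5,
                       err_rate = 0.001, lowq_rate = 0.02,
                       extension_fraction = 0.20,
                       slip_rate = 0.01, flip_rate = 0.01,
                       background_rate = 0.2, read_len = 100L,
                       n_arrays = 5000L, strict_pam = TRUE,
                       barcodes = c("TAGC", "CTGA", "GACT", "AGTC"),
                       umi_len = 5L,
                       anchor = "AGATCGGAAGAGC",
                       leader_len = 60L,
                       repeat_seq = "GTGTTCCCCGCGCCAGCGGGGATAAACCG") {
  cfg <- as.list(environment())
  probs <- c(gc = gc, pcr_dup_p = pcr_dup_p, err_rate = err_rate,
             lowq_rate = lowq_rate, extension_fraction = extension_fraction,
             slip_rate = slip_rate, flip_rate = flip_rate,
             background_rate = background_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities must lie in [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (pcr_dup_p >= 1) stop("pcr_dup_p must be < 1")
  if (decay_lambda <= 0) stop("decay_lambda must be > 0")
  if (pps_pos < 10000L || genome_len - pps_pos < 10000L)
    stop("pps_pos must leave >= 10 kb of genome on each side")
  if (locus_pos + 1000L >= pps_pos - site_window)
    stop("locus_pos must lie outside the protospacer sampling window")
  check_dna(c(barcodes, anchor, repeat_seq))
  structure(cfg, class = "sim_config")
}

# FragSeq read layout: [barcode][umi5][insert][umi3][anchor][pad].
fragseq_layout <- function(cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config()
  list(barcode_len = nchar(cfg$barcodes[[1L]]),
       umi_len = as.integer(cfg$umi_len),
       anchor = cfg$anchor)
}

random_kmers <- function(n, k) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Substitution errors + per-base qualities for a vector of read sequences.
add_noise <- function(seqs, err_rate, lowq_rate) {
  n <- length(seqs)
  qual <- character(n)
  out <- seqs
  for (i in seq_len(n)) {
    L <- nchar(out[i])
    q <- sample(30:40, L, replace = TRUE)
    if (lowq_rate > 0) {
      low <- which(stats::runif(L) < lowq_rate)
      if (length(low)) q[low] <- sample(2:19, length(low), replace = TRUE)
    }
    if (err_rate > 0) {
      ne <- stats::rbinom(1L, L, err_rate)
      if (ne > 0) {
        pos <- sample.int(L, ne)
        ch <- strsplit(out[i], "", fixed = TRUE)[[1L]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        out[i] <- paste(ch, collapse = "")
      }
    }
    qual[i] <- intToUtf8(q + 33L)
  }
  list(seq = out, qual = qual)
}

#' Build a synthetic self-targeting reference
#'
#' Generates a random genome at the configured GC content, embeds a CRISPR
#' locus (leader, repeat, targeting spacer, repeat) at `locus_pos`, and
#' plants the priming protospacer -- whose sequence equals the targeting
#' spacer, flanked by the consensus PAM -- at `pps_pos` on the top strand
#' (so the top strand is the nontarget strand).
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `genome` ([genome_ref()]), `locus`
#'   ([crispr_locus()]), `pps` ([pps()]), and `locus_iv` (the interval
#'   occupied by the array).
#' @export
make_reference <- function(cfg) {
  set.seed(cfg$seed)
  preset <- cfg$preset
  L <- preset$spacer_len
  m <- nchar(preset$pam)
  n_out <- m - preset$pam_inside

  g <- random_dna(cfg$genome_len, cfg$gc)
  leader <- random_dna(cfg$leader_len, cfg$gc)
  # spacer begins with the inside-PAM bases (e.g. the G of AAG for I-E)
  inside <- if (preset$pam_inside > 0L)
    substr(preset$pam, m - preset$pam_inside + 1L, m) else ""
  spacer <- paste0(inside, random_dna(L - preset$pam_inside, cfg$gc))
  locus <- crispr_locus(leader, cfg$repeat_seq, spacer, preset)

  array_seq <- paste0(leader, cfg$repeat_seq, spacer, cfg$repeat_seq)
  substr(g, cfg$locus_pos + 1L, cfg$locus_pos + nchar(array_seq)) <- array_seq

  # plant PAM (outside bases) + protospacer at pps_pos on the top strand
  outside <- substr(preset$pam, 1L, n_out)
  site <- paste0(outside, spacer)
  substr(g, cfg$pps_pos - n_out + 1L, cfg$pps_pos + L) <- site

  genome <- genome_ref(c(sim_chr = g))
  ps_iv <- interval("sim_chr", cfg$pps_pos, cfg$pps_pos + L, "+")
  stopifnot(has_consensus_pam(genome, ps_iv, preset))
  list(genome = genome, locus = locus,
       pps = pps(ps_iv, pam_interval_for(ps_iv, preset)),
       locus_iv = interval("sim_chr", cfg$locus_pos,
                           cfg$locus_pos + nchar(array_seq), "+"))
}

#' Select protospacer sites around the PPS
#'
#' Samples `n_sites` consensus-PAM protospacer sites on each side of the
#' PPS within `site_window`, on the strand dictated by the preset's
#' orientation mode: for I-E, upstream (PAM-proximal) sites lie on the
#' nontarget strand and downstream sites on the target strand; for I-F the
#' assignment is reversed. Site usage weights are
#' `exp(-distance / decay_lambda) * Lognormal(0, site_weight_sigma)`,
#' normalised to sum to 1.
#'
#' @param genome a [genome_ref()].
#' @param pps_obj a [pps()].
#' @param cfg a [sim_config()].
#' @return a data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `side` ("upstream"/"downstream"), `dist`, `weight`.
#' @export
select_protospacers <- function(genome, pps_obj, cfg) {
  set.seed(cfg$seed + 1L)
  preset <- cfg$preset
  L <- preset$spacer_len
  m <- nchar(preset$pam)
  n_out <- m - preset$pam_inside
  contig <- pps_obj$protospacer$contig
  s <- contig_seq(genome, contig)
  ps_start <- pps_obj$protospacer$start
  ps_end <- pps_obj$protospacer$end
  guard <- 50L

  # PAM-proximal (upstream) side: where the PPS PAM sits
  pam_left <- pps_obj$pam_interval$start < ps_start
  # protospacer starts (0-based) of all consensus-PAM sites per strand
  plus_pam <- start(matchPattern(DNAString(preset$pam), DNAString(s))) - 1L
  plus_sites <- plus_pam + n_out
  minus_pam <- start(matchPattern(DNAString(revcomp(preset$pam)),
                                  DNAString(s))) - 1L
  minus_end <- minus_pam + m - n_out     # protospacer end (exclusive)
  minus_sites <- minus_end - L

  nt_strand <- pps_obj$protospacer$strand   # nontarget strand
  t_strand <- setdiff(c("+", "-"), nt_strand)
  up_strand <- if (preset$orientation_mode == "IE") nt_strand else t_strand
  down_strand <- if (preset$orientation_mode == "IE") t_strand else nt_strand

  pick <- function(region) {
    side <- if ((region == "left") == pam_left) "upstream" else "downstream"
    strand <- if (side == "upstream") up_strand else down_strand
    if (region == "left") {
      lo <- max(0L, ps_start - cfg$site_window)
      hi <- ps_start - guard - L
    } else {
      lo <- ps_end + guard
      hi <- min(nchar(s) - L, ps_end + cfg$site_window - L)
    }
    cand <- if (strand == "+") plus_sites else minus_sites
    cand <- cand[cand >= lo & cand <= hi]
    ok <- has_consensus_pam_many(genome, contig, cand, cand + L,
                                 rep(strand, length(cand)), preset)
    cand <- cand[ok]
    if (length(cand) < cfg$n_sites)
      stop("too few consensus-PAM sites on the ", side, " side (",
           length(cand), " < ", cfg$n_sites, ")")
    st <- sort(sample(cand, cfg$n_sites))
    data.frame(contig = contig, start = st, end = st + L, strand = strand,
               side = side,
               dist = if (region == "left") ps_start - (st + L)
                      else st - ps_end,
               stringsAsFactors = FALSE)
  }
  sites <- rbind(pick("left"), pick("right"))
  if (!cfg$strict_pam) {
    # relaxed mode: admit a minority of arbitrary (PAM-free) windows
    n_extra <- max(1L, round(0.1 * cfg$n_sites))
    xs <- sample(seq(ps_end + guard, ps_end + cfg$site_window - L), n_extra)
    sites <- rbind(sites, data.frame(
      contig = contig, start = xs, end = xs + L,
      strand = sample(c("+", "-"), n_extra, replace = TRUE),
      side = "downstream", dist = xs - ps_end, stringsAsFactors = FALSE))
  }
  w <- exp(-sites$dist / cfg$decay_lambda) *
    stats::rlnorm(nrow(sites), 0, cfg$site_weight_sigma)
  sites$weight <- w / sum(w)
  sites
}

#' Emit ground-truth prespacer duplexes
#'
#' Draws `n_duplexes` duplex molecules across the selected sites in
#' proportion to their weights. Per molecule the duplex (short-strand)
#' length is drawn from the preset's `duplex_len_choices`; the long strand
#' always spans the full `long_len` footprint on the opposite strand, so
#' the 3' overhang on the PAM-derived end is `long_len - duplex_len` and
#' the PAM-distal end is blunt.
#'
#' @param sites site table from [select_protospacers()].
#' @param cfg a [sim_config()].
#' @return a data.frame of class `"duplex_truth"`, one row per distinct
#'   (site, duplex length) with a `copies` count. Coordinates:
#'   `short_start/short_end/short_strand`, `long_start/long_end/long_strand`,
#'   the strandless paired footprint `duplex_start/duplex_end`, `overhang`,
#'   `pam_side` ("left"/"right" in top-strand coordinates), `side`.
#' @export
emit_duplexes <- function(sites, cfg) {
  if (nrow(sites) == 0L) stop("no sites supplied")
  set.seed(cfg$seed + 2L)
  preset <- cfg$preset
  L <- preset$spacer_len
  idx <- sample.int(nrow(sites), cfg$n_duplexes, replace = TRUE,
                    prob = sites$weight)
  dlen <- preset$duplex_len_choices$len[
    sample.int(nrow(preset$duplex_len_choices), cfg$n_duplexes,
               replace = TRUE, prob = preset$duplex_len_choices$prob)]
  tab <- as.data.frame(table(site = idx, dlen = dlen), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  si <- as.integer(as.character(tab$site))
  d <- as.integer(as.character(tab$dlen))
  ext <- d - L                       # extension of the short strand into the PAM
  lext <- preset$long_len - L        # extension of the long strand
  plus <- sites$strand[si] == "+"
  out <- data.frame(
    contig = sites$contig[si],
    site_start = sites$start[si], site_end = sites$end[si],
    site_strand = sites$strand[si], side = sites$side[si],
    duplex_len = d,
    short_start = ifelse(plus, sites$start[si] - ext, sites$start[si]),
    short_end = ifelse(plus, sites$end[si], sites$end[si] + ext),
    short_strand = sites$strand[si],
    long_start = ifelse(plus, sites$start[si] - lext, sites$start[si]),
    long_end = ifelse(plus, sites$end[si], sites$end[si] + lext),
    long_strand = ifelse(plus, "-", "+"),
    overhang = preset$long_len - d,
    pam_side = ifelse(plus, "left", "right"),
    copies = tab$Freq,
    stringsAsFactors = FALSE)
  out$duplex_start <- out$short_start
  out$duplex_end <- out$short_end
  class(out) <- c("duplex_truth", "data.frame")
  out
}

#' Simulate a FragSeq library from ground-truth duplexes
#'
#' Each strand of each duplex copy becomes one single-stranded sequencing
#' molecule with layout `[barcode][UMI5][insert][UMI3][3'-adapter anchor]`,
#' padded with random sequence to `read_len`. Molecules are PCR-duplicated
#' `1 + Geometric(1 - pcr_dup_p)` times; substitution errors are applied at
#' `err_rate` and a `lowq_rate` fraction of bases receive Phred < 20.
#' Unstructured background degradation fragments (uniform 20-60 nt, at
#' exponentially decaying distance from the PPS) are mixed in so that they
#' make up `background_rate` of all molecules.
#'
#' @param truth a `duplex_truth` table from [emit_duplexes()].
#' @param genome a [genome_ref()].
#' @param cfg a [sim_config()].
#' @param pps_obj a [pps()] (anchors the background fragment distribution).
#' @return a list with `reads` (data.frame `id`, `seq`, `qual`) and
#'   `manifest` (list with `duplexes` and a per-molecule `molecules` table;
#'   every read id is `<mol_id>_r<k>`).
#' @export
synthesize_fragseq_reads <- function(truth, genome, cfg, pps_obj) {
  set.seed(cfg$seed + 3L)
  layout <- fragseq_layout(cfg)
  min_len <- layout$barcode_len + 2L * layout$umi_len + nchar(layout$anchor) + 1L
  if (cfg$read_len < min_len)
    stop("read_len ", cfg$read_len, " is shorter than the minimum layout (",
         min_len, " nt)")

  n_pre <- sum(truth$copies)
  rows <- rep(seq_len(nrow(truth)), truth$copies)
  mol <- data.frame(
    origin = rep(c("prespacer_short", "prespacer_long"), each = length(rows)),
    truth_row = c(rows, rows),
    contig = truth$contig[c(rows, rows)],
    start = c(truth$short_start[rows], truth$long_start[rows]),
    end = c(truth$short_end[rows], truth$long_end[rows]),
    strand = c(truth$short_strand[rows], truth$long_strand[rows]),
    stringsAsFactors = FALSE)

  if (cfg$background_rate > 0) {
    n_bg <- round(cfg$background_rate / (1 - cfg$background_rate) * nrow(mol))
    if (n_bg > 0L) {
      contig <- pps_obj$protospacer$contig
      clen <- nchar(contig_seq(genome, contig))
      center <- (pps_obj$protospacer$start + pps_obj$protospacer$end) %/% 2L
      off <- round(stats::rexp(n_bg, 1 / cfg$decay_lambda)) *
        sample(c(-1L, 1L), n_bg, replace = TRUE)
      len <- sample(20:60, n_bg, replace = TRUE)
      st <- pmin(pmax(center + off, 0L), clen - 61L)
      mol <- rbind(mol, data.frame(
        origin = "background", truth_row = NA_integer_, contig = contig,
        start = st, end = st + len,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        stringsAsFactors = FALSE))
    }
  }
  n_mol <- nrow(mol)
  mol$mol_id <- sprintf("mol%06d", seq_len(n_mol))
  mol$insert <- extract_seq_many(genome, mol$contig[1L], mol$start, mol$end,
                                 mol$strand)
  mol$umi5 <- random_kmers(n_mol, layout$umi_len)
  mol$umi3 <- random_kmers(n_mol, layout$umi_len)
  mol$barcode <- sample(cfg$barcodes, n_mol, replace = TRUE)
  mol$n_copies <- 1L + stats::rgeom(n_mol, 1 - cfg$pcr_dup_p)

  ridx <- rep(seq_len(n_mol), mol$n_copies)
  core <- paste0(mol$barcode[ridx], mol$umi5[ridx], mol$insert[ridx],
                 mol$umi3[ridx], layout$anchor)
  pad_n <- pmax(0L, cfg$read_len - nchar(core))
  pads <- vapply(pad_n, random_dna, "", gc = 0.5)
  seqs <- substr(paste0(core, pads), 1L, cfg$read_len)
  noisy <- add_noise(seqs, cfg$err_rate, cfg$lowq_rate)
  rep_no <- sequence(mol$n_copies)
  reads <- data.frame(id = sprintf("%s_r%d", mol$mol_id[ridx], rep_no),
                      seq = noisy$seq, qual = noisy$qual,
                      stringsAsFactors = FALSE)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  row.names(reads) <- NULL
  list(reads = reads,
       manifest = list(duplexes = truth, molecules = mol))
}

#' Simulate CRISPR-array amplicon reads
#'
#' An `extension_fraction` of reads carry an extended array
#' (leader tail + repeat + new spacer + repeat + preexisting spacer head);
#' the rest are nonextended (single repeat). New spacers are drawn from the
#' same site-weight map used for prespacer duplexes, enabling
#' fragment/spacer abundance correlation tests. A `slip_rate` fraction of
#' acquisitions is shifted 1-3 nt off the canonical site and a `flip_rate`
#' fraction is inserted as the reverse complement.
#'
#' @param sites site table from [select_protospacers()].
#' @param locus a [crispr_locus()].
#' @param genome a [genome_ref()].
#' @param cfg a [sim_config()].
#' @return a list with `reads` and a per-read `manifest` data.frame
#'   (`id`, `extended`, `site_row`, `artifact`, `spacer_true`).
#' @export
synthesize_array_amplicons <- function(sites, locus, genome, cfg) {
  set.seed(cfg$seed + 4L)
  n <- cfg$n_arrays
  extended <- stats::runif(n) < cfg$extension_fraction
  site_row <- rep(NA_integer_, n)
  artifact <- rep("none", n)
  spacer <- rep(NA_character_, n)
  ne <- sum(extended)
  if (ne > 0L) {
    si <- sample.int(nrow(sites), ne, replace = TRUE, prob = sites$weight)
    site_row[extended] <- si
    u <- stats::runif(ne)
    art <- ifelse(u < cfg$slip_rate, "slippage",
                  ifelse(u < cfg$slip_rate + cfg$flip_rate, "flippage", "none"))
    artifact[extended] <- art
    st <- sites$start[si]; en <- sites$end[si]; sd <- sites$strand[si]
    slip <- art == "slippage"
    if (any(slip)) {
      sh <- sample(c(-3:-1, 1:3), sum(slip), replace = TRUE)
      st[slip] <- st[slip] + sh
      en[slip] <- en[slip] + sh
    }
    sp <- extract_seq_many(genome, sites$contig[1L], st, en, sd)
    flip <- art == "flippage"
    if (any(flip)) sp[flip] <- revcomp(sp[flip])
    spacer[extended] <- sp
  }
  leader_tail <- substr(locus$leader, max(1L, nchar(locus$leader) - 24L),
                        nchar(locus$leader))
  old_head <- substr(locus$spacers[[1L]], 1L, 20L)
  seqs <- ifelse(extended,
                 paste0(leader_tail, locus$repeat_seq, spacer,
                        locus$repeat_seq, old_head),
                 paste0(leader_tail, locus$repeat_seq, old_head))
  noisy <- add_noise(seqs, cfg$err_rate, cfg$lowq_rate)
  ids <- sprintf("arr%06d", seq_len(n))
  list(reads = data.frame(id = ids, seq = noisy$seq, qual = noisy$qual,
                          stringsAsFactors = FALSE),
       manifest = data.frame(id = ids, extended = extended,
                             site_row = site_row, artifact = artifact,
                             spacer_true = spacer, stringsAsFactors = FALSE))
}

#' Simulate prespacer-efficiency assay amplicons
#'
#' Emits array amplicon reads in which a configured fraction of arrays
#' carry the oligo's properly processed 33-nt core in direct or reverse
#' orientation, a fraction carry an improperly processed (shifted) spacer,
#' and the rest are nonextended. A `lowq_read_frac` fraction of reads
#' contain at least one base with Phred < 14 (and are expected to be
#' removed by [filter_assay_reads()]).
#'
#' @param oligo_top top-strand sequence of the electroporated oligo; must
#'   contain an `AA|G` processing site with a full 33-nt core (see
#'   [oligo_core()]).
#' @param params list of assay parameters: `n_reads` (default 2000),
#'   `frac_direct` (0.10), `frac_reverse` (0), `frac_improper` (0),
#'   `lowq_read_frac` (0.05), `err_rate` (0.001), and `locus` (a
#'   [crispr_locus()]; required).
#' @param seed integer seed.
#' @return a list with `reads` and per-read `manifest` (`id`, `category`).
#' @export
synthesize_assay_reads <- function(oligo_top, params, seed = 1L) {
  set.seed(seed)
  p <- utils::modifyList(list(n_reads = 2000L, frac_direct = 0.10,
                              frac_reverse = 0, frac_improper = 0,
                              lowq_read_frac = 0.05, err_rate = 0.001),
                         params)
  if (is.null(p$locus)) stop("params$locus (a crispr_locus) is required")
  core <- oligo_core(oligo_top)
  fr <- c(direct = p$frac_direct, reverse = p$frac_reverse,
          improper = p$frac_improper)
  if (sum(fr) > 1) stop("category fractions exceed 1")
  cat_ <- sample(c(names(fr), "nonextended"), p$n_reads, replace = TRUE,
                 prob = c(fr, 1 - sum(fr)))
  improper_sp <- if (core$g_pos > 1L)
    substr(oligo_top, core$g_pos - 1L, core$g_pos + 31L)
  else substr(oligo_top, core$g_pos + 1L, core$g_pos + 33L)
  ins <- c(direct = core$seq, reverse = revcomp(core$seq),
           improper = improper_sp)[cat_]
  locus <- p$locus
  leader_tail <- substr(locus$leader, max(1L, nchar(locus$leader) - 24L),
                        nchar(locus$leader))
  old_head <- substr(locus$spacers[[1L]], 1L, 20L)
  seqs <- ifelse(cat_ == "nonextended",
                 paste0(leader_tail, locus$repeat_seq, old_head),
                 paste0(leader_tail, locus$repeat_seq, ins,
                        locus$repeat_seq, old_head))
  noisy <- add_noise(seqs, p$err_rate, lowq_rate = 0)
  # inject sub-14 quality bases into a fraction of reads
  lowq <- which(stats::runif(p$n_reads) < p$lowq_read_frac)
  for (i in lowq) {
    q <- utf8ToInt(noisy$qual[i]) - 33L
    pos <- sample.int(length(q), sample(1:3, 1L))
    q[pos] <- sample(2:13, length(pos), replace = TRUE)
    noisy$qual[i] <- intToUtf8(q + 33L)
  }
  ids <- sprintf("asy%06d", seq_len(p$n_reads))
  list(reads = data.frame(id = ids, seq = noisy$seq, qual = noisy$qual,
                          stringsAsFactors = FALSE),
       manifest = data.frame(id = ids, category = cat_,
                             stringsAsFactors = FALSE))
}

#' Simulate aligned genomic-DNA read positions with PPS-region depletion
#'
#' Emulates the genomic consequence of self-targeting: uniform sequencing
#' depth with a Gaussian-shaped depletion centred on the PPS, returned as a
#' table of aligned read intervals suitable for [binned_coverage()].
#'
#' @param genome a [genome_ref()].
#' @param pps_obj a [pps()].
#' @param n_reads number of reads before depletion thinning.
#' @param read_len aligned read length.
#' @param depletion_depth maximum fraction of reads removed at the PPS.
#' @param depletion_sigma Gaussian width (nt) of the depleted region.
#' @param seed integer seed.
#' @return a data.frame of aligned intervals (`contig`, `start`, `end`,
#'   `strand`, `abundance`).
#' @export
simulate_genomic_depth <- function(genome, pps_obj, n_reads = 20000L,
                                   read_len = 150L, depletion_depth = 0.8,
                                   depletion_sigma = 8000, seed = 1L) {
  set.seed(seed)
  contig <- pps_obj$protospacer$contig
  clen <- nchar(contig_seq(genome, contig))
  st <- sample.int(clen - read_len, n_reads, replace = TRUE) - 1L
  center <- (pps_obj$protospacer$start + pps_obj$protospacer$end) / 2
  keep_p <- 1 - depletion_depth *
    exp(-((st + read_len / 2) - center)^2 / (2 * depletion_sigma^2))
  keep <- stats::runif(n_reads) < keep_p
  data.frame(contig = contig, start = st[keep], end = st[keep] + read_len,
             strand = sample(c("+", "-"), sum(keep), replace = TRUE),
             abundance = 1L, stringsAsFactors = FALSE)
}
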