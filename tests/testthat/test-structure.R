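toy_pps <- function() {
  # protospacer on + at [100, 133) with PAM on the left
  pps(interval("chr", 100, 133, "+"), interval("chr", 98, 101, "+"))
}

frag_row <- function(start, end, strand, abundance = 1L) {
  data.frame(contig = "chr", start = start, end = end, strand = strand,
             length = end - start, abundance = abundance, mismatches = 0)
}

test_that("classify_fragments assigns strand role and PAM-proximal side", {
  p <- toy_pps()
  up_nt <- classify_fragments(frag_row(40L, 73L, "+"), p)
  expect_identical(up_nt$strand_role, "NT")
  expect_identical(up_nt$side, "upstream")
  up_t <- classify_fragments(frag_row(40L, 73L, "-"), p)
  expect_identical(up_t$strand_role, "T")
  expect_identical(up_t$side, "upstream")
  down <- classify_fragments(frag_row(200L, 233L, "+"), p)
  expect_identical(down$side, "downstream")
  # fragment straddling the PPS: classified by midpoint and flagged
  over <- classify_fragments(frag_row(90L, 140L, "+"), p)
  expect_true(over$pps_overlap)
  expect_identical(over$side, "upstream")  # midpoint 115 < PPS midpoint 116.5
  over2 <- classify_fragments(frag_row(95L, 145L, "+"), p)
  expect_identical(over2$side, "downstream")
})

test_that("length_distribution weights by abundance and summarises replicates", {
  tb <- rbind(frag_row(10L, 43L, "+", 5L), frag_row(50L, 83L, "+", 2L),
              frag_row(10L, 47L, "-", 4L))
  ld <- length_distribution(tb)
  expect_identical(ld$length, c(33L, 37L))
  expect_equal(ld$mean, c(7, 4))
  expect_true(all(is.na(ld$sem)))
  # single fragment: delta histogram
  d1 <- length_distribution(frag_row(10L, 43L, "+"))
  expect_identical(nrow(d1), 1L)
  # identical replicates have zero SEM
  ld3 <- length_distribution(list(tb, tb, tb))
  expect_equal(ld3$sem, c(0, 0))
  expect_identical(nrow(length_distribution(tb[0, ])), 0L)
})

test_that("end_pfm windows are strand-aware with offset 0 at the anchored base", {
  g <- genome_ref(c(chr = "ACGTACGTTAGCAAGGTTTT"))
  # one + fragment [12, 17): 5' end base at 12 ("A" of AAGG)
  pfm <- end_pfm(frag_row(12L, 17L, "+"), g, "five_prime",
                 length_range = c(5L, 5L), window = c(-2L, 3L))
  expect_identical(dim(pfm$counts), c(4L, 6L))
  expect_identical(colnames(pfm$counts), as.character(-2:3))
  # genome around the anchor: GC|AAGGT -> offsets -2..3 = G,C,A,A,G,G
  expect_equal(unname(pfm$counts["A", c("0", "1")]), c(1, 1))
  expect_equal(unname(pfm$counts["G", c("-2", "2", "3")]), c(1, 1, 1))
  expect_equal(unname(pfm$counts["C", "-1"]), 1)
  # same fragment on the minus strand: 5' end at position 16, read on -
  pfm_m <- end_pfm(frag_row(12L, 17L, "-"), g, "five_prime",
                   length_range = c(5L, 5L), window = c(-2L, 2L))
  # genome [12,17) = AAGGT; on minus the 5' base is A (revcomp T at pos 16)
  expect_equal(unname(pfm_m$counts["A", "0"]), 1)
  expect_equal(unname(pfm_m$counts["A", "-1"]), 1)  # pos 17 is T -> A on minus
  # default logo windows both span 26 columns
  p5 <- end_pfm(frag_row(12L, 17L, "+"), g, "five_prime", c(5L, 5L),
                c(-10L, 15L))
  expect_identical(ncol(p5$counts), 26L)
  p3 <- end_pfm(frag_row(12L, 17L, "+"), g, "three_prime", c(5L, 5L),
                c(-20L, 5L))
  expect_identical(ncol(p3$counts), 26L)
  # off-contig windows are skipped and counted
  expect_identical(p5$n_skipped, 1)
  expect_identical(p3$n_skipped, 1)
})

test_that("PFM columns conserve counts and frequencies normalise", {
  s <- ie_sim()
  pfm <- end_pfm(s$tab, s$ref$genome, "five_prime", c(32L, 34L),
                 c(-10L, 15L))
  expect_true(all(colSums(pfm$counts) <= pfm$n))
  f <- pfm_freq(pfm)
  expect_equal(unname(colSums(f)), rep(1, 26))
})

test_that("call_pam reports contiguous high-information runs", {
  # constructed: every sequence carries AAG at offsets -2..0
  counts <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"),
                                            as.character(-3:2)))
  counts[, ] <- 5
  counts[, "-2"] <- c(40, 0, 0, 0); counts[, "-1"] <- c(40, 0, 0, 0)
  counts["G", "0"] <- 40; counts[c("A", "C", "T"), "0"] <- 0
  pfm <- structure(list(counts = counts, n = 40, n_skipped = 0,
                        window = c(-3L, 2L), anchor = "five_prime"),
                   class = "pfm")
  pam <- call_pam(pfm)
  expect_identical(pam$motifs$motif, "AAG")
  expect_identical(pam$motifs$offset_start, -2L)
  expect_identical(pam$motifs$offset_end, 0L)
  # uniform PFM yields no motif
  uni <- pfm; uni$counts[, ] <- 10
  expect_identical(nrow(call_pam(uni)$motifs), 0L)
  small <- pfm; small$n <- 10
  expect_error(call_pam(small), "insufficient data")
})

test_that("pair_duplexes emits calls only for blunt-ended 3'-overhang pairs", {
  set.seed(5)
  g <- genome_ref(c(chr = random_dna(300)))
  tb <- rbind(frag_row(100L, 133L, "+", 7L),   # short strand
              frag_row(96L, 133L, "-", 3L),    # long strand, 4-nt overhang
              frag_row(98L, 135L, "-", 2L),    # no shared end with A
              frag_row(200L, 233L, "-", 4L),   # short on minus
              frag_row(200L, 237L, "+", 6L))   # long, blunt left end
  calls <- pair_duplexes(tb, g, system_preset("IE"))
  expect_identical(nrow(calls), 2L)
  left <- calls[calls$pam_side == "left", ]
  expect_identical(left$duplex_start, 100L)
  expect_identical(left$duplex_end, 133L)
  expect_identical(left$overhang, 4L)
  expect_identical(left$support_short, 7L)
  expect_identical(left$support_long, 3L)
  expect_identical(left$ps_start, 100L)
  expect_identical(left$ps_strand, "+")
  right <- calls[calls$pam_side == "right", ]
  expect_identical(right$overhang, 4L)
  expect_identical(right$duplex_end, 233L)
  expect_identical(right$ps_strand, "-")
  # the unpaired fragment is reported
  expect_identical(attr(calls, "unpaired")$start, 98L)
})

test_that("noise-free simulation recovers every truth duplex exactly once", {
  nf <- noise_free_sim()
  tk <- paste(nf$truth$short_start, nf$truth$short_end, nf$truth$pam_side)
  ck <- paste(nf$calls$duplex_start, nf$calls$duplex_end, nf$calls$pam_side)
  expect_true(all(tk %in% ck))
  expect_true(all(table(ck) == 1L))
  expect_identical(sort(unique(nf$calls$overhang)), sort(unique(nf$truth$overhang)))
  # supports match the manifest copy counts per strand interval
  ex <- nf$calls[1L, ]
  tr <- nf$truth[nf$truth$short_start == ex$duplex_start &
                 nf$truth$short_end == ex$duplex_end, ]
  expect_identical(ex$support_short, sum(tr$copies))
})

test_that("IE parameter recovery: modal lengths, overhangs and PAM", {
  s <- ie_sim()
  calls <- s$calls
  w_mode <- function(x, w) as.integer(names(which.max(tapply(w, x, sum))))
  expect_identical(w_mode(calls$short_len, calls$support_short), 33L)
  expect_identical(w_mode(calls$long_len, calls$support_long), 37L)
  oh33 <- calls[calls$short_len == 33L, ]
  expect_identical(w_mode(oh33$overhang, oh33$support_short), 4L)
  oh34 <- calls[calls$short_len == 34L, ]
  expect_identical(w_mode(oh34$overhang, oh34$support_short), 3L)
  # upstream short strands are overwhelmingly nontarget-strand-derived
  up_short <- s$tab[s$tab$side == "upstream" & s$tab$length %in% 32:34, ]
  ab <- tapply(up_short$abundance, up_short$strand_role, sum)
  expect_gt(ab[["NT"]], 5 * sum(ab) / 10)
  pfm <- end_pfm(s$tab, s$ref$genome, "five_prime", c(33L, 33L),
                 c(-10L, 15L))
  pam <- call_pam(pfm)
  expect_true("AAG" %in% pam$motifs$motif)
})

test_that("IF preset mirrors the orientation and gives 5-nt overhangs", {
  sf <- if_sim()
  w_mode <- function(x, w) as.integer(names(which.max(tapply(w, x, sum))))
  expect_identical(w_mode(sf$calls$overhang, sf$calls$support_short), 5L)
  # upstream short strands now derive from the target strand (reversed bias)
  up_short <- sf$tab[sf$tab$side == "upstream" & sf$tab$length %in% 31:33, ]
  ab <- tapply(up_short$abundance, up_short$strand_role, sum)
  expect_gt(ab[["T"]], 5 * sum(ab) / 10)
})

test_that("correlations behave on collinear, anti-collinear and simulated data", {
  base <- pair_duplexes(rbind(frag_row(100L, 133L, "+", 1L)),
                        toy_genome(), system_preset("IE"))[0, ]
  mk <- function(ss, sl) {
    df <- base[0, ]
    for (i in seq_along(ss))
      df <- rbind(df, data.frame(contig = "chr", duplex_start = i * 50L,
                                 duplex_end = i * 50L + 33L, overhang = 4L,
                                 pam_side = "left", short_len = 33L,
                                 long_len = 37L, support_short = ss[i],
                                 support_long = sl[i], pam_seq = "AAG",
                                 ps_start = i * 50L, ps_end = i * 50L + 33L,
                                 ps_strand = "+"))
    df
  }
  expect_equal(complementary_abundance_correlation(mk(1:3, c(2, 4, 6))), 1)
  expect_equal(complementary_abundance_correlation(mk(1:3, c(3, 2, 1))), -1)
  expect_error(complementary_abundance_correlation(mk(1:2, 1:2)), ">= 3")
  expect_error(complementary_abundance_correlation(mk(c(1, 1, 1), 1:3)),
               "zero variance")
  # shared site usage induces a positive strand-abundance correlation
  expect_gt(complementary_abundance_correlation(ie_sim()$calls), 0)
})

test_that("fragment and spacer abundances correlate through shared site weights", {
  s <- ie_sim()
  cfg <- s$cfg
  arr <- synthesize_array_amplicons(s$sites, s$ref$locus, s$ref$genome,
                                    sim_config(seed = 23L, n_arrays = 3000L))
  masked <- mask_low_quality(arr$reads, 20L)
  sp <- unlist(lapply(masked$seq, extract_spacers,
                      repeat_seq = s$ref$locus$repeat_seq))
  recs <- filter_slippage_flippage(map_spacers(sp, s$ref$genome, cfg$preset))
  kept <- recs[recs$status == "mapped" & !recs$slippage & !recs$flippage, ]
  r <- fragment_spacer_correlation(s$calls, kept)
  expect_gt(as.numeric(r), 0)
  expect_gt(attr(r, "n_joined"), 10L)
  # spacer counts proportional to total duplex support give r = 1
  calls_self <- s$calls
  key <- paste(calls_self$ps_start, calls_self$ps_end, calls_self$ps_strand)
  supp <- tapply(calls_self$support_short + calls_self$support_long, key, sum)
  pick <- names(sort(supp, decreasing = TRUE))[1:5]
  calls_sub <- calls_self[key %in% pick, ]
  fake_rec <- do.call(rbind, lapply(pick, function(k) {
    parts <- strsplit(k, " ")[[1]]
    data.frame(seq = "x", status = "mapped", contig = "sim_chr",
               start = rep(as.integer(parts[1]), supp[[k]]),
               end = as.integer(parts[2]), strand = parts[3],
               pam_ok = TRUE, slippage = FALSE, flippage = FALSE)
  }))
  expect_equal(as.numeric(fragment_spacer_correlation(calls_sub, fake_rec)),
               1)
  # disjoint intervals: undefined correlation
  far <- fake_rec; far$start <- far$start + 1L
  expect_error(fragment_spacer_correlation(calls_sub, far), "no protospacers")
})
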