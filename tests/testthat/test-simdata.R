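test_that("make_reference is seed-deterministic and plants the PPS invariants", {
  cfg <- sim_config(seed = 1L)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(r1$genome$seqs, r2$genome$seqs)
  expect_identical(extract_seq(r1$genome, r1$pps$protospacer),
                   r1$locus$spacers[[1L]])
  expect_true(has_consensus_pam(r1$genome, r1$pps$protospacer, cfg$preset))
  # the array embeds leader + repeat + spacer + repeat at locus_pos
  arr <- extract_seq(r1$genome, r1$locus_iv)
  expect_identical(arr, paste0(r1$locus$leader, r1$locus$repeat_seq,
                               r1$locus$spacers[[1L]], r1$locus$repeat_seq))
})

test_that("sim_config validates probabilities and PPS placement", {
  expect_error(sim_config(err_rate = 1.5), "\\[0,1\\]")
  expect_error(sim_config(decay_lambda = 0), "decay_lambda")
  expect_error(sim_config(pps_pos = 5000L), "10 kb")
  expect_error(sim_config(pcr_dup_p = 1), "pcr_dup_p")
})

test_that("selected sites all carry the consensus PAM with the orientation rule", {
  s <- ie_sim()
  sites <- s$sites
  expect_true(all(has_consensus_pam_ok <- vapply(seq_len(nrow(sites)),
    function(i) has_consensus_pam(s$ref$genome,
      interval(sites$contig[i], sites$start[i], sites$end[i],
               sites$strand[i]), s$cfg$preset), logical(1))))
  # I-E: upstream sites on the nontarget (PPS) strand, downstream on target
  nt <- s$ref$pps$protospacer$strand
  expect_true(all(sites$strand[sites$side == "upstream"] == nt))
  expect_true(all(sites$strand[sites$side == "downstream"] != nt))
  expect_equal(sum(sites$weight), 1)
})

test_that("switching IE to IF on a fixed seed swaps upstream/downstream strands", {
  se <- ie_sim()$sites
  sf <- if_sim()$sites
  nt_e <- ie_sim()$ref$pps$protospacer$strand
  nt_f <- if_sim()$ref$pps$protospacer$strand
  expect_identical(nt_e, nt_f)
  expect_true(all(se$strand[se$side == "upstream"] == nt_e))
  expect_true(all(sf$strand[sf$side == "upstream"] != nt_f))
  expect_true(all(sf$strand[sf$side == "downstream"] == nt_f))
})

test_that("site weights decay exponentially with distance from the PPS", {
  # with zero lognormal dispersion the decay is exact: log w = const - d/lambda
  cfg <- sim_config(seed = 13L, site_weight_sigma = 0,
                    decay_lambda = 4000)
  ref <- make_reference(cfg)
  sites <- select_protospacers(ref$genome, ref$pps, cfg)
  fit <- stats::lm(log(weight) ~ dist, data = sites)
  expect_equal(unname(stats::coef(fit)[["dist"]]), -1 / 4000,
               tolerance = 1e-6)
  # with dispersion, the decay is recovered on average (weights at distance
  # 0 and lambda differ by factor e)
  cfg2 <- sim_config(seed = 14L, site_weight_sigma = 1, decay_lambda = 4000)
  ref2 <- make_reference(cfg2)
  sites2 <- select_protospacers(ref2$genome, ref2$pps, cfg2)
  fit2 <- stats::lm(log(weight) ~ dist, data = sites2)
  se <- summary(fit2)$coefficients["dist", "Std. Error"]
  expect_lt(abs(stats::coef(fit2)[["dist"]] + 1 / 4000), 4 * se)
})

test_that("emitted duplexes obey the blunt-end / overhang geometry", {
  s <- ie_sim()
  tr <- s$truth
  preset <- s$cfg$preset
  expect_identical(sum(tr$copies), s$cfg$n_duplexes)
  # long minus short length equals the overhang; one end is shared (blunt)
  expect_true(all((tr$long_end - tr$long_start) -
                  (tr$short_end - tr$short_start) == tr$overhang))
  expect_true(all(tr$long_end - tr$long_start == preset$long_len))
  blunt_right <- tr$pam_side == "left"
  expect_true(all(tr$short_end[blunt_right] == tr$long_end[blunt_right]))
  expect_true(all(tr$short_start[!blunt_right] == tr$long_start[!blunt_right]))
  # the overhang extends past the short strand on the PAM side
  expect_true(all(tr$short_start[blunt_right] -
                  tr$long_start[blunt_right] == tr$overhang[blunt_right]))
  # PAM consensus holds at every truth protospacer
  ok <- has_consensus_pam_many(s$ref$genome, "sim_chr", tr$site_start,
                               tr$site_end, tr$site_strand, preset)
  expect_true(all(ok))
  # worked coordinate example: 33-bp duplex at a plus-strand site [p, p+33)
  ex <- tr[tr$site_strand == "+" & tr$duplex_len == 33L, ][1L, ]
  expect_identical(ex$short_start, ex$site_start)
  expect_identical(ex$long_start, ex$site_start - 4L)
  expect_identical(ex$overhang, 4L)
  ex34 <- tr[tr$site_strand == "+" & tr$duplex_len == 34L, ][1L, ]
  expect_identical(ex34$short_start, ex34$site_start - 1L)
  expect_identical(ex34$overhang, 3L)
})

test_that("IF duplexes have a 5-nt overhang", {
  tr <- if_sim()$truth
  expect_true(all(tr$overhang == 5L))
  expect_true(all(tr$long_end - tr$long_start == 37L))
})

test_that("FragSeq library: noise-free inserts match the genome and PCR follows the geometric model", {
  nf <- noise_free_sim()
  mol <- nf$frag$manifest$molecules
  ref_seq <- vapply(seq_len(nrow(mol)), function(i)
    extract_seq(nf$ref$genome, interval(mol$contig[i], mol$start[i],
                                        mol$end[i], mol$strand[i])), "")
  expect_identical(mol$insert, ref_seq)
  expect_true(all(mol$n_copies == 1L))  # pcr_dup_p = 0
  # geometric duplication: mean copies over many molecules ~ 1/(1 - p)
  cfg <- sim_config(seed = 31L, n_duplexes = 2500L, pcr_dup_p = 0.4,
                    err_rate = 0, lowq_rate = 0)
  ref <- make_reference(cfg)
  sites <- select_protospacers(ref$genome, ref$pps, cfg)
  truth <- emit_duplexes(sites, cfg)
  fr <- synthesize_fragseq_reads(truth, ref$genome, cfg, ref$pps)
  ncop <- fr$manifest$molecules$n_copies
  expect_gt(length(ncop), 5000L)
  se <- stats::sd(ncop) / sqrt(length(ncop))
  expect_lt(abs(mean(ncop) - 1 / 0.6), 3 * se)
  # every read id traces to exactly one manifest molecule
  mid <- sub("_r\\d+$", "", fr$reads$id)
  expect_true(all(mid %in% fr$manifest$molecules$mol_id))
})

test_that("FragSeq FASTQ output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 8L, n_duplexes = 60L)
  run <- function() {
    ref <- make_reference(cfg)
    sites <- select_protospacers(ref$genome, ref$pps, cfg)
    truth <- emit_duplexes(sites, cfg)
    synthesize_fragseq_reads(truth, ref$genome, cfg, ref$pps)$reads
  }
  expect_identical(run(), run())
})

test_that("array amplicons hit the configured extension fraction and artifact rates", {
  s <- ie_sim()
  cfg <- s$cfg
  arr <- synthesize_array_amplicons(s$sites, s$ref$locus, s$ref$genome,
                                    sim_config(seed = 1L, n_arrays = 5000L))
  man <- arr$manifest
  # empirical extension fraction within 3 binomial SE of 0.20
  p_hat <- mean(man$extended)
  se <- sqrt(0.2 * 0.8 / nrow(man))
  expect_lt(abs(p_hat - 0.20), 3 * se)
  # extension_fraction = 0: no read carries two repeats
  arr0 <- synthesize_array_amplicons(s$sites, s$ref$locus, s$ref$genome,
    sim_config(seed = 18L, n_arrays = 300L, extension_fraction = 0,
               err_rate = 0, lowq_rate = 0))
  n2 <- vapply(arr0$reads$seq, function(x)
    length(find_repeat_sites(x, s$ref$locus$repeat_seq)), integer(1))
  expect_true(all(n2 == 1L))
  # extension_fraction = 1, no artifacts: every extended read carries a
  # consensus-PAM spacer
  arr1 <- synthesize_array_amplicons(s$sites, s$ref$locus, s$ref$genome,
    sim_config(seed = 19L, n_arrays = 200L, extension_fraction = 1,
               slip_rate = 0, flip_rate = 0, err_rate = 0, lowq_rate = 0))
  sp <- unlist(lapply(arr1$reads$seq, extract_spacers,
                      repeat_seq = s$ref$locus$repeat_seq))
  expect_length(sp, 200L)
  recs <- map_spacers(sp, s$ref$genome, cfg$preset)
  expect_true(all(recs$status == "mapped"))
  expect_true(all(recs$pam_ok))
})

test_that("assay reads hit the configured direct fraction; reverse-only yields the revcomp core", {
  ol <- symmetric_oligo()
  locus <- ie_sim()$ref$locus
  sim <- synthesize_assay_reads(ol$top, list(locus = locus, n_reads = 2000L,
                                             frac_direct = 0.10), seed = 4L)
  p_hat <- mean(sim$manifest$category == "direct")
  expect_lt(abs(p_hat - 0.10), 3 * sqrt(0.1 * 0.9 / 2000))
  # reverse-only: every extracted spacer equals revcomp of the direct core
  simr <- synthesize_assay_reads(ol$top,
    list(locus = locus, n_reads = 100L, frac_direct = 0, frac_reverse = 1,
         err_rate = 0, lowq_read_frac = 0), seed = 5L)
  sp <- unlist(lapply(simr$reads$seq, extract_spacers,
                      repeat_seq = locus$repeat_seq))
  expect_true(all(sp == revcomp(ol$core)))
  # seeded determinism
  expect_identical(
    synthesize_assay_reads(ol$top, list(locus = locus, n_reads = 50L),
                           seed = 6L),
    synthesize_assay_reads(ol$top, list(locus = locus, n_reads = 50L),
                           seed = 6L))
})
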