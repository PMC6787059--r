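# Shared fixtures and independent oracles, built in code at test time.

# Small genome with a planted consensus-PAM protospacer for refmodel tests.
toy_genome <- function(seed = 101, len = 300L) {
  set.seed(seed)
  genome_ref(c(chr = random_dna(len)))
}

# Brute-force ungapped aligner: scans every offset of both strands and
# counts mismatches by raw byte comparison. Independent of align_unique.
brute_align <- function(insert, gseq, kmax = 2L) {
  L <- nchar(insert)
  n <- nchar(gseq)
  if (L > n) return(data.frame(start = integer(), strand = character()))
  offs <- 0:(n - L)
  subs <- substring(gseq, offs + 1L, offs + L)
  count_mm <- function(pat) {
    pr <- charToRaw(pat)
    vapply(subs, function(s) sum(charToRaw(s) != pr), integer(1L),
           USE.NAMES = FALSE)
  }
  mmf <- count_mm(insert)
  mmr <- count_mm(revcomp(insert))
  sf <- offs[mmf <= kmax]
  sr <- offs[mmr <= kmax]
  rbind(data.frame(start = sf, strand = rep("+", length(sf))),
        data.frame(start = sr, strand = rep("-", length(sr))))
}

# Memoised simulation runs shared across test files (one R session per
# test_dir run); keeps the default study conditions at reduced scale.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  ref <- make_reference(cfg)
  sites <- select_protospacers(ref$genome, ref$pps, cfg)
  truth <- emit_duplexes(sites, cfg)
  fr <- synthesize_fragseq_reads(truth, ref$genome, cfg, ref$pps)
  pipe <- fragseq_pipeline(fr$reads, ref$genome)
  tab <- classify_fragments(pipe$table, ref$pps, cfg$preset)
  calls <- pair_duplexes(tab, ref$genome, cfg$preset)
  out <- list(cfg = cfg, ref = ref, sites = sites, truth = truth,
              frag = fr, pipe = pipe, tab = tab, calls = calls)
  .sim_cache[[key]] <- out
  out
}

ie_sim <- function() {
  cached_sim("ie", sim_config(n_duplexes = 400L, seed = 3L))
}

if_sim <- function() {
  cached_sim("if", sim_config(n_duplexes = 400L, seed = 3L,
                              preset = system_preset("IF")))
}

noise_free_sim <- function() {
  cached_sim("nf", sim_config(n_duplexes = 150L, seed = 9L, err_rate = 0,
                              lowq_rate = 0, pcr_dup_p = 0,
                              background_rate = 0))
}

# Full-scale study-condition runs used by the acceptance suite.
accept_ie <- function() cached_sim("accept_ie", sim_config(seed = 42L))
accept_if <- function() cached_sim("accept_if",
  sim_config(seed = 42L, preset = system_preset("IF")))

# Abundance-weighted mode.
w_mode <- function(x, w) as.integer(names(which.max(tapply(w, x, sum))))

# Array-amplicon run large enough to accumulate mapped slippage/flippage
# artifacts for detection-rate checks; memoised (shared with acceptance).
artifact_run <- function() {
  if (!is.null(.sim_cache[["artifact"]])) return(.sim_cache[["artifact"]])
  s <- ie_sim()
  cfg_a <- sim_config(seed = 37L, n_arrays = 12000L)
  arr <- synthesize_array_amplicons(s$sites, s$ref$locus, s$ref$genome,
                                    cfg_a)
  masked <- mask_low_quality(arr$reads, 20L)
  spl <- lapply(masked$seq, extract_spacers,
                repeat_seq = s$ref$locus$repeat_seq)
  ridx <- rep(seq_along(spl), lengths(spl))
  recs <- filter_slippage_flippage(map_spacers(unlist(spl), s$ref$genome,
                                               s$cfg$preset))
  out <- list(recs = recs, artifact = arr$manifest$artifact[ridx],
              mapped = recs$status == "mapped")
  .sim_cache[["artifact"]] <- out
  out
}

# Assay oligo designed so that its reverse complement carries the mirrored
# AA|G processing site (core' == revcomp(core)): prefix ends AA, core ends
# C, suffix starts TT.
symmetric_oligo <- function(seed = 7) {
  set.seed(seed)
  core <- paste0("G", random_dna(31L), "C")
  list(top = paste0("CCAA", core, "TTGC"), core = core)
}

# Printed prespacer-oligo spacer used in the worked example.
DIRECT_33 <- "GCCCAATTTACTACTCGTTCTGGTGTTTCTCGT"
REVERSE_33 <- "ACGAGAAACACCAGAACGAGTAGTAAATTGGGC"

# High-quality Phred string.
hiq <- function(n) strrep(intToUtf8(40L + 33L), n)
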