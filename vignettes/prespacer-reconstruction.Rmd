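---
title: "Reconstructing prespacer structures from strand-specific fragment sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing prespacer structures from strand-specific fragment sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragseqr)
```

## The biological model

In type I CRISPR-Cas systems, interference and adaptation are coupled:
degradation of DNA around a priming protospacer (PPS) feeds the Cas1-Cas2
integrase with short DNA duplexes -- *prespacers* -- that become new
spacers in the CRISPR array. fragseqr models and analyses the structural
signature of these intermediates in an *E. coli*-like type I-E system:

* **Prespacer duplexes.** A prespacer is an asymmetric duplex: a paired
  region of 33 or 34 bp whose PAM-distal end is blunt and whose
  PAM-derived end carries a 3' single-stranded overhang of 4 or 3 nt, so
  that the overhang-bearing ("long") strand always spans 37 nt. The
  duplex is excised within a 5'-AAG-3' PAM, cut between AA and G, which
  places the G of the PAM as the first protospacer base. The type I-F
  preset keeps the same blunt-plus-3'-overhang architecture with a 32-nt
  spacer and a 5-nt overhang.
* **Orientation.** The nontarget strand (NT) is the strand whose sequence
  matches the targeting crRNA spacer. In the I-E system, protospacers
  upstream (PAM-proximal side) of the PPS place their short strand on the
  nontarget strand and downstream sites on the target strand; the I-F
  preset reverses this bias.
* **Usage gradient.** Protospacer usage decays with distance from the PPS.
  The simulator draws site weights as
  $w_i \propto e^{-d_i/\lambda}\,\mathrm{Lognormal}(0,\sigma)$, one shared
  weight map for both the prespacer ensemble and the acquired-spacer
  ensemble, which is what makes the fragment/spacer abundance correlation
  a meaningful end-to-end check.

Strand-specific sequencing of short fragments without tailing preserves
both fragment ends at single-nucleotide resolution. The analysis therefore
never needs to model nuclease chemistry: duplexes are reconstructed purely
from end coordinates, by pairing a plus-strand fragment $[a_1,a_2)$ with a
minus-strand fragment $[b_1,b_2)$ when they share one blunt end and the
longer strand protrudes at its 3' terminus ($a_2=b_2,\ b_1<a_1$, overhang
on the left; or $a_1=b_1,\ a_2>b_2$, overhang on the right).

## Pipeline stages and their contracts

1. **Quality masking** (`mask_low_quality`): bases with Phred < 20 become
   N. N is never allowed to *support* a call downstream: it is a mismatch
   in alignment and is excluded from consensus votes and PFM counts.
2. **Adapter/UMI parsing** (`parse_reads`): the read layout is
   `[barcode 4][UMI 5][insert][UMI 5][13-nt 3'-adapter anchor][pad]`. The
   anchor is located with at most one mismatch; failures are recorded as
   rejection *data* (`no_adapter`, `empty_insert`), not errors, so that
   read accounting stays exact at every stage.
3. **PCR-duplicate consensus** (`cluster_consensus`): reads are grouped by
   the exact (UMI5, UMI3, insert length) combination; within a group,
   single-linkage clusters join inserts at Hamming distance <= 1 (N
   matches anything for clustering only). Each cluster yields one
   molecule whose insert is the positionwise majority; ties give N --
   the pipeline never invents a base.
4. **Unique ungapped alignment** (`align_unique`): an end-to-end scan of
   both genome strands accepts an insert iff *exactly one*
   position/strand attains <= 2 mismatches, with the 16-100 nt length
   filter. This is deliberately stricter than a best-versus-second-best
   margin: for short degradation fragments, any second near-match makes
   the locus assignment unreliable. Indels are rejected as `no_hit`.
5. **Structure inference**: abundance-weighted length histograms,
   end-anchored position frequency matrices, duplex pairing, and the
   fragment/spacer abundance correlations.

## Numerical and convention choices

* **Coordinates** are 0-based, half-open, top-strand; the 5' terminus of a
  `+` feature is `start`, of a `-` feature `end - 1`.
* **PFM offsets.** In `end_pfm`, offset 0 is the anchored terminal base of
  the fragment, negative offsets run in the fragment's 5' direction. The
  default windows (-10, +15) around 5' ends and (-20, +5) around 3' ends
  each span 26 columns. Under this convention the I-E PAM appears as a
  run of >1-bit columns at offsets -2..0 reading AAG, with the G (offset
  0) being the first protospacer base.
* **Which fragments feed the PAM logo.** The package calls the PAM on the
  *modal* short-strand length class (33 nt for I-E). Stacking mixed 33-
  and 34-nt fragments on their 5' ends smears the PAM across two
  alignments (the 34-nt strand begins one base earlier), which dilutes
  the outermost A below the 1-bit threshold by construction -- a property
  of the alignment convention, not of the data. The modal class gives a
  clean, threshold-stable motif.
* **IC threshold** 1.0 bit per column (uniform background), the
  conventional logo-significance choice; configurable in `call_pam`.
* **Duplex pairing tolerance** defaults to 0 (exact end matching): UMI
  consensus upstream absorbs sequencing errors, so relaxing the blunt-end
  match mainly admits background pairings. A `tol` knob exists.
* **Slippage/flippage filter.** The canonical set is the mapped,
  consensus-PAM records. A non-canonical record is flagged `slippage`
  when shifted 1-5 nt from a canonical interval on the same strand, and
  `flippage` when it reverse-complements onto a canonical interval with
  >= 90% overlap. These windows are this package's operationalisation of
  the filter (configurable), and flagged counts are always reported.
* **Coverage smoothing** is degree-1 loess with tricube weights, span
  0.05 of the bins, with a 99% pointwise normal-approximation band. The
  span is a package default chosen for 1-kb bins over ~100-kb simulated
  genomes.
* **Fragments overlapping the PPS** are classified by midpoint and
  flagged, since neither side label is well defined for them.

## What the simulator emulates -- and what it does not

`sim_config()` defaults define the study conditions: a 100-kb genome at
50% GC; the PPS at position 60,000 on the top (nontarget) strand; 40
consensus-PAM protospacer sites per side within 25 kb, weights decaying
with scale $\lambda = 5000$ nt and lognormal dispersion $\sigma = 1$;
2,000 prespacer duplex molecules with duplex lengths drawn 33:34 = 0.7:0.3
(I-E); adapter+UMI libraries with geometric PCR overamplification
(`pcr_dup_p = 0.5`, mean 2 reads/molecule); substitution errors at
0.1% per base and 2% of bases below Q20; 20% unstructured background
degradation fragments (20-60 nt, exponentially decaying distance from the
PPS); CRISPR arrays extended at 20% with 1% slippage and 1% flippage
artifacts; and a ~10% direct integration fraction in the prespacer
efficiency assay. One seed drives every stage (each stage uses a small
fixed offset so stages are reproducible in isolation).

The simulator does **not** emulate: ligation-bias or GC-bias of library
preparation, indel sequencing errors, chimeric PCR products,
replication-origin coverage trends, long-strand end heterogeneity (the
long strand is always exactly 37 nt; real libraries show 36-38-nt
spread), or plasmid/phage biology. Passing tests therefore demonstrate
that the *inference machinery* recovers the planted structural model
under realistic noise -- not that every property of real libraries is
reproduced.

The CRISPR repeat default is the *E. coli* K-12 consensus repeat and the
leader is random sequence; both are configuration, not claims about any
particular strain. The adapter/UMI dialect (4-nt barcode, two 5-nt UMIs,
13-nt anchor) is likewise the package's own declared layout.

## Problem sizes

The shipped tests run the full pipeline at 2,000 duplex molecules per
preset and 5,000-12,000 array amplicons -- sizes at which the modal
structural quantities (33-bp duplex, 4-nt overhang, 37-nt long strand,
5-nt overhang for I-F, >95% PAM fraction) are stable across seeds, while
a complete run of the suite stays in the minutes range on one CPU. The
same computations at larger scale only narrow the sampling noise; the
modes themselves are already deterministic consequences of the planted
geometry.

## Known limitations

* Exact (UMI5, UMI3, insert length) grouping splits clusters when a UMI
  base is error-masked to N, inflating molecule counts by a few percent
  under the default quality profile. Structural calls are mode-based and
  unaffected; noise-free runs conserve molecules exactly.
* Uniqueness is defined as "exactly one position with <= k mismatches",
  so a genuine locus with a single near-duplicate elsewhere is discarded
  (`ambiguous`) rather than rescued by a margin rule.
* `fragment_spacer_correlation` joins on identical protospacer intervals
  only; acquisition events shifted by slippage do not join even when they
  originate from the same site.
* The prespacer-efficiency analysis scores "arrays" as filtered reads
  spanning the leader-repeat junction; with a different amplicon design
  the denominator must be reconsidered.
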