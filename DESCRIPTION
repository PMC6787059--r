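Package: fragseqr
Title: Reconstruction of CRISPR Prespacer Structures from Strand-Specific
    Fragment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying primed CRISPR adaptation from sequencing
    data. Implements a strand-specific fragment sequencing (FragSeq style)
    analysis pipeline that reconstructs spacer-precursor duplexes (duplex
    length, PAM, 3'-overhang structure and strand/side orientation) from
    short-fragment libraries, together with companion analyses of newly
    acquired spacers in CRISPR-array amplicons, prespacer integration
    efficiency assays, and binned genome coverage with local-regression
    smoothing. A read simulator for type I-E and I-F self-targeting systems
    generates reference genomes, ground-truth prespacer ensembles and FASTQ
    libraries with manifests, so every stage of the pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
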