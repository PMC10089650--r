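Package: tescape
Title: Transposable Element Landscape and Genomic Ecology Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytics for repeat-annotated genomes centred on the interplay of
    endogenous retroviruses (ERVs) and LINE retrotransposons. Parses
    RepeatMasker-style repeat tables, computes CpG-corrected Kimura 2-parameter
    divergence and divergence-binned TE landscapes, DNA-loss coefficients,
    LTR-identity dating and autonomy classification of ERV subfamilies,
    detection of ERV insertions that interrupt LINEs via consensus-coordinate
    conjoining with seeded permutation nulls, strand-aware upstream enrichment
    with a segmental-duplication confound check, ERV hotspot calling, and
    KRAB-zinc-finger duplicate-age analysis. Ships a synthetic-genome generator
    with a ground-truth manifest so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
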