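Package: embryocirc
Title: Circular RNA Discovery and Absolute Transcript Quantification for
    Single-Embryo Total RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis toolkit for single-embryo total RNA-seq
    (SUPeR-seq style) libraries spanning a pre-implantation developmental
    series. Annotates exonic circular RNAs from chimeric alignments with
    exact splice-site matching and a pair-end linearity check, estimates
    absolute mRNA and circRNA copy numbers per embryo from a dual spike-in
    design (an ERCC-style dilution panel plus a three-species long-polyA
    mix), computes junction-level circular-to-linear statistics, classifies
    genes as maternal or zygotic across the series with mRNA-content-aware
    size factors and a negative-binomial test, filters de novo transcript
    candidates, and analyses circRNA genomic features (exon counts and
    lengths, flanking-intron lengths, repeat-element enrichment). Includes
    a fully seeded synthetic embryo-series generator with ground truth for
    every stage of the pipeline, and an end-to-end pipeline runner with a
    run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
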