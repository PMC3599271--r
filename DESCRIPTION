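Package: mycotrans
Title: Comparative Confrontation Transcriptomics of Mycoparasitic Trichoderma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-confrontation transcriptomics of
    Trichoderma species challenged with a prey fungus (Rhizoctonia solani).
    Implements two-colour tiling-microarray processing (flag filtering,
    global Lowess normalization without background subtraction, dye-swap
    merging, strand-aware probe-to-transcript aggregation and threshold
    regulation calls with moderated statistics), conservation-class and
    FunCat regulation summaries, orthogroup-based cross-species Venn
    comparison and stage kinetics, genomic cluster-density scanning with a
    permutation null, and confrontation-plate / qPCR assay metrics
    (growth inhibition, overgrowth, amplification efficiency, Livak
    fold changes). A synthetic-data generator with planted ground truth
    emulates the statistical structure of confrontation tiling-array
    experiments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
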