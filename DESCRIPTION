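Package: rbtnfit
Title: Essentiality and Fitness Analysis for Randomly Barcoded Transposon
    Insertion Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for randomly barcoded transposon insertion sequencing
    (RB-TnSeq) screens in bacteria with mariner-family transposons that
    insert at TA dinucleotides. Implements barcode-map validation,
    per-gene insertion statistics, essential-gene candidate calling with
    gene-terminus exclusion and repeat masking by self-similarity
    clustering, reciprocal-best-hit cross-strain concordance, per-gene
    fitness scoring between paired timepoints by depth-matched multinomial
    resampling and a rank-sum test with replicate combination,
    multi-condition refinement of significant gene sets, COG-category and
    polysaccharide-utilization-locus enrichment accounting, TPM expression
    ranking, in-silico arithmetic for invertible-promoter orientation
    assays, and a synthetic barcoded-library simulator with known ground
    truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, Sequencing, FunctionalGenomics, Microbiome, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
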