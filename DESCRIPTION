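Package: affopt
Title: Affinity-Optimizing Enhancer Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring transcription-factor binding sites by protein
    binding microarray (PBM) 8-mer relative affinity, scanning enhancer
    sequences for degenerate ETS, AP-1 and IRF core motifs on both strands,
    classifying single-nucleotide variants by the fold change in binding
    affinity they induce, and testing whether affinity-optimizing variants
    are enriched for gain-of-function expression in massively parallel
    reporter assay (MPRA) and eQTL association tables. Also includes a
    ChIP-signal versus affinity correlation stage and a synthetic-data
    generator with known ground truth so every pipeline stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    stringi,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
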