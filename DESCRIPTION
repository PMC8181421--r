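Package: atacmem
Title: Identification and Tracking of Epigenetically Primed Chromatin in Memory T Cells from ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying and tracking epigenetically
    primed chromatin regions in antigen-specific memory T cells from ATAC-seq
    data. Builds replicate-concordant peak sets from Tn5 cut-site tracks with a
    local-Poisson caller, normalizes summit-window counts with top-N-median
    correction factors, tests differential accessibility with a
    negative-binomial Wald test, classifies peaks into memory-gained (mDHS),
    naive-lost (nDHS), antigen-induced (iDHS) and antigen-diminished (dDHS)
    categories, summarizes their stability across timepoints, integrates peak
    categories with differential gene expression, scores consensus-motif
    enrichment and strand-resolved transcription-factor footprints, and ships a
    truth-labelled synthetic data generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
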