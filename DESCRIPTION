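Package: enhancerReprog
Title: Cross-Species Classification of Enhancer Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of enhancer evolution between two species.
    Projects tissue-labelled enhancers through pairwise alignment chains and
    classifies each as functionally conserved (FCE), reprogrammed (RPE) or
    gained (EG); scans enhancer sequences for transcription factor binding
    motifs with exact log-odds p-values and tests motif overrepresentation
    against length/GC/repeat-matched controls with a Poisson model; labels
    each binding site in an orthologous enhancer pair as conserved,
    reshuffled, gained or reused and compares site densities between
    reprogrammed and conserved enhancers; builds midpoint-bounded gene loci
    and tests whether reprogramming shifts flanking-gene expression. Includes
    a two-species scenario simulator with planted ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
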