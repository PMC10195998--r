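Package: neuroinduct
Title: Temporal Transcriptional Analysis of Neural Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-course transcriptomics of neural
    induction of pluripotent stem cells. Implements fold-change based
    temporal differential-expression calling against a reference time
    point, ChIP-seq promoter-window transcription-factor target
    derivation with stage-specific set subtraction, preranked gene set
    enrichment (weighted Kolmogorov-Smirnov running sum with a
    gene-permutation null) and exact hypergeometric overrepresentation,
    confidence-thresholded interaction-network module detection with
    cross-series module conservation, and knockdown effect ranking that
    contrasts time-course induction with knockdown-versus-control fold
    changes. A synthetic-data generator with known ground truth (planted
    differential genes, planted TF-target structure, planted network
    communities, simulated knockdown) supports end-to-end recovery
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
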