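Package: loopForge
Title: Prediction of Cohesin-Mediated Chromatin Loops from 1D Chromatin Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds labeled sets of cohesin (RAD21)-mediated chromatin loops
    from replicated ChIA-PET interaction calls and distance-matched negative
    loops assembled from ChIP-seq peak pairs, quantifies chromatin-feature
    read tracks in 1500 bins across the 3L extended loop region, trains and
    evaluates six supervised classifiers on the resulting feature matrices,
    extracts position-resolved feature-importance profiles from the
    tree-based learners, and applies trained models across cell lines.
    Includes a synthetic-data generator emulating replicated loop calls,
    anchor peak sets with decoys, and enriched read tracks so the whole
    pipeline is testable without external downloads.
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
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    rpart,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dense-net.R'
    'loopset-methods.R'
    'feature-matrix.R'
    'classify.R'
    'importance.R'
    'synthetic-data.R'
    'io.R'
    'loop-sets.R'
    'loopForge-package.R'
    'pipeline.R'
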