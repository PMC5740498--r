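Package: dmsmap
Title: Deep Mutational Scanning Variant-Effect Maps from Complementation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building complete variant-effect maps from pooled
    functional complementation screens. Covers design of NNK codon-replacement
    mutagenic oligonucleotides, barcode-sequencing (BarSeq) fitness estimation
    from competitive growth time courses with Bayesian regularization of
    replicate variances, tiled-amplicon sequencing (TileSeq) enrichment-ratio
    scoring with wild-type-control error subtraction, monotone cross-platform
    rescaling and confidence-weighted joining of scores, random-forest
    imputation and refinement of missense maps, clinical evaluation utilities
    (diploid scoring, Mann-Whitney U, precision-recall, reference-bracketed
    classification), and a full synthetic-data generator providing ground
    truth for every scoring stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
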