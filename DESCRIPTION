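Package: hgtecology
Title: Eco-Evolutionary Analysis of Horizontal Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects well-supported horizontal gene transfer (HGT) events by
    aggregating gene-tree/species-tree reconciliation replicates, and relates
    transfer rates to the ecology of the exchanging taxa: gene ubiquity within
    pangenomes (extended core/shell/cloud), functional category enrichment on
    a species-distance by gene-distance grid, co-occurrence corrected for
    phylogenetic signal through a power-law model, abundance tiers, and an
    entropy-based habitat generalism index. Includes a synthetic community
    generator that plants each of these effects with known parameters so every
    pipeline stage can be validated against ground truth, plus
    distribution-matched subsampling utilities for covariate normalisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
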