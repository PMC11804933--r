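Package: rbpduet
Title: Joint Analysis of a Pair of RNA-Binding Proteins from iCLIP, Conservation, Coevolution and smFISH Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analyses for two RNA-binding proteins (RBPs) profiled by
    iCLIP across developmental stages. Provides expression-normalized cross-link
    occupancy scoring and temporal profile clustering; binding-site interval
    statistics (Jaccard index, relative-distance correlation index, per-gene
    footprint overlap); conservation scoring of binding sites against shuffled-site
    nulls; binding-site coevolution via mutual information with average product
    correction; and steady-state mRNA half-life estimation from single-molecule
    FISH nascent/mature counts. A seeded synthetic-data module generates every
    input the pipeline consumes, so all stages are testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    IRanges,
    Biostrings,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
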