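Package: netcontrast
Title: Cross-Species Contrast of Hormone-Responsive Pathway Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares transcriptional responses between two species with a
    threshold-based differential-expression caller for no-replicate RNA-seq
    designs, reciprocal-best-hit homology mapping from similarity hit tables,
    merging of pathway collections into a global functional-interaction
    network with hub and degree-distribution statistics, and a
    label-permutation z-score test for differential-expression enrichment in
    the graph neighborhood of seed genes. Includes a synthetic-data generator
    with planted ground truth so every stage of the pipeline can be exercised
    and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
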