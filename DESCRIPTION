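Package: colonyscreen
Title: Colony-Array Screen Quantification and Differential Growth Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pinned colony-array chemical-genomics
    screens, from grayscale plate photographs (or simulated plates with known
    ground truth) to hit calls and downstream set statistics. Implements
    grid-based colony quantification by iterative center refinement and
    border walking, log2/quantile/cyclic-LOESS normalization of integrated
    colony densities, an empirical-Bayes regularized t-test with a ranked
    background-variance window, Benjamini-Hochberg adjustment and multi-day
    hit calling, hypergeometric overlap scans against compiled external
    gene-score datasets, DAG-aware conditional gene-set enrichment, and
    Jaccard-weighted enrichment-map export. A synthetic-data module generates
    plate images, density tables, correlated external datasets, and toy
    ontologies so the whole pipeline is testable without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    tiff,
    png,
    igraph,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
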