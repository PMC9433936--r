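Package: granufi
Title: Granule-Based Stress Filtering for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and removes transcriptionally stressed cells from
    single-cell RNA-seq datasets without manual gating. Cells are scored for
    gene-set activity with expression-binned control genes, partitioned into
    small clusters ("granules" of roughly 100-200 cells) by a
    resolution-searched shared-nearest-neighbor Louvain clustering, and
    granule-averaged scores are thresholded by a data-driven cutoff obtained
    from a Gaussian fit using the median location and a lower-tail scale
    estimate. Positive (stress) and negative (lineage) gene-set criteria are
    combined to call and filter stressed cells. Includes a negative-binomial
    simulator with a planted stressed subpopulation for offline testing, a
    10x-convention MatrixMarket reader, and a GMT gene-set parser.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    tools,
    igraph,
    RANN,
    irlba,
    uwot,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
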