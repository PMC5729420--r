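Package: monster
Title: Modeling Network State Transitions from Expression and Regulatory Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers phenotype-specific bipartite transcription factor (TF) to
    gene regulatory networks from expression data and a binary motif prior,
    estimates the TF-by-TF transition matrix that maps the initial-state
    network onto the final-state network by columnwise least squares (with
    optional ridge or lasso penalties), and ranks transcription factors by
    differential TF involvement (dTFI) with a sample-label permutation null,
    z-based p-values, and Benjamini-Hochberg false discovery rates. Includes
    a synthetic-data generator with known TF-target rewiring for end-to-end
    validation, and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
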