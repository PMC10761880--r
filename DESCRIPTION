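Package: cycifith
Title: Single-Cell Cyclic Immunofluorescence Analysis and Intratumor
    Heterogeneity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed tissue-imaging (CyCIF)
    single-cell data: watershed nuclear segmentation with fixed boundary
    expansion, per-cell marker quantification, two-component
    Gaussian-mixture and local-minimum gating, multi-level antibody
    concordance qualification, Gaussian-mixture phenotype clustering with
    t-SNE embedding, per-patient intratumor-heterogeneity statistics (the
    cluster-composition GMM score and the embedding-dispersion t-SNE
    score), and recurrence-association tests (rank tests and Cox
    proportional-hazards models). Includes a synthetic-cohort simulator
    with known ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    FNN,
    jsonlite,
    mclust,
    Rtsne,
    stats,
    survival,
    tiff,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
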