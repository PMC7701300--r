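Package: mfmda
Title: Graph-Regularized Matrix Factorization for miRNA-Disease
    Association Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts unobserved miRNA-disease associations by
    graph-regularized nonnegative matrix factorization of a binary
    association matrix, integrating MeSH-derived disease semantic
    similarity, miRNA functional similarity, and Gaussian
    interaction-profile kernels. Provides multiplicative-update model
    fitting, global fivefold and leave-one-disease-out cross-validation
    with ROC/PR evaluation, per-disease candidate ranking, a synthetic
    benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
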