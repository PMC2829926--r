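Package: cachexsig
Title: Discovery and Validation of Weight-Loss-Associated Muscle Gene Signatures
Version: 0.1.0
Authors@R:
    person("Muscle", "Transcriptomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering skeletal-muscle gene
    signatures that covary with a continuous clinical trait (percentage
    weight loss in cancer cachexia). Implements quantitative significance
    analysis of microarrays (permutation-FDR d-statistic), an empirical
    Bayes moderated regression test, FDR-bounded intersection of the two
    procedures, subject clustering on the recovered signature, qRT-PCR
    delta-Ct cross-platform validation, and promoter motif
    over/under-representation analysis by log-ratio position-weight-matrix
    scanning with Fisher and Z-score statistics. Includes a synthetic-data
    generator emulating the statistical structure of such studies so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
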