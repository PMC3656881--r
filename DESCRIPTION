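Package: sh2pep
Title: Semi-Supervised Prediction of SH2 Domain-Phosphopeptide Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-domain prediction of SH2 domain binding to
    phosphotyrosine-containing peptides from imbalanced high-throughput
    interaction data. Peptide windows centered on the phosphotyrosine are
    one-hot encoded and classified with regularized polynomial-kernel
    support vector machines, so that non-additive dependencies between
    ligand positions can be modeled. Severely imbalanced training sets are
    rebalanced by an iterative self-training procedure that mines
    confidently non-binding peptides from a large unlabeled pool.
    Includes dataset compilation from affinity measurements, a nested
    cross-validation model-selection protocol, a position-specific
    scoring matrix baseline with relative-score thresholding, a filtered
    proteome scanning stage, and a synthetic-data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
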