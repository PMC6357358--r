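Package: pathdrive
Title: Pathway Activity Inference and Drug-Sensitivity Modelling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised single-sample pathway activity scoring from
    log-scale gene expression (DiffRank rank-difference statistic, combined
    Z-score, PLAGE singular-vector meta-genes, and GSVA kernel/random-walk
    enrichment), pathway-collection diagnostics (Jaccard overlap, median
    absolute pairwise correlation with permutation tests), elastic-net
    modelling of drug response on pathway activities with a cross-validated
    alpha/lambda grid search, downstream drug-mechanism evaluation
    (drug-gene pathway categories, method comparison, sensitive-vs-resistant
    activity tests), and a latent-factor synthetic data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
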