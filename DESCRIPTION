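Package: crisprembed
Title: Prior-Initialized Embedding Models for CRISPR/Cas9 Off-Target
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hybrid-driven prediction of CRISPR/Cas9 off-target activity
    from guide/target sequence pairs. Two literature-style priors -- a
    mismatch tolerance profile (MTP) and DNA-RNA interaction contribution
    scores (DRICS) -- initialize trainable position-by-pairing embedding
    spaces that are optimized jointly with a small Inception/BiLSTM
    network; sub-model probabilities are combined by mean fusion.
    Includes per-sgRNA AUPRC/AUROC evaluation, exact one-sided Wilcoxon
    signed-rank comparison across random seeds, a seed-vote analysis of
    embedding updates (position distributions, weighted mismatch
    similarity, cross-dataset concordance), and a synthetic-data
    generator with planted position-by-mismatch effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
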