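Package: foldboost
Title: Two-Stage RNA Secondary Structure Prediction by Deep Ensemble
    Boosting and Soft-Constrained Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts nested RNA secondary structures with a two-stage
    pipeline. Stage 1 encodes a sequence together with the structures
    proposed by a panel of six single-sequence folding engines into an
    l x 10 tensor and labels, with a convolutional encoder, residual
    multi-head self-attention and a transpose-convolution decoder, the
    probability that each nucleotide is paired in the final structure.
    Stage 2 converts those probabilities into SHAPE-like reactivities
    (S = 1 - Y), maps them to Deigan pseudoenergies, and folds the
    sequence by pseudoenergy-augmented minimum-free-energy dynamic
    programming. Includes self-contained folding engines (Nussinov,
    Zuker-style with stacking, McCaskill partition function with
    maximum-expected-accuracy decoding), masked weighted cross-entropy
    training with family-wise cross-validation, pair- and label-level
    evaluation metrics with league-table summaries, and a synthetic
    RNA structural-family generator with compensatory mutations so the
    whole pipeline is testable without external data or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
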