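Package: pts1pred
Title: Plant PTS1 Peroxisomal Protein Prediction from C-Terminal Sequence
    Features
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts plant PTS1-type peroxisomal proteins from the last
    residues of a protein sequence. Position-specific amino-acid
    probability profiles are estimated separately for peroxisomal and
    non-peroxisomal training sets and combined into bi-profile Bayes
    feature vectors, which drive both a naive-Bayes log-odds baseline and
    a soft-margin support vector machine with a radial-basis kernel and a
    tunable decision cut-off. Includes stratified k-fold cross-validation
    with accuracy, sensitivity, specificity and Matthews correlation
    coefficient, cut-off and window-length sweeps, per-position
    composition contrasts, a greedy redundancy filter, a synthetic
    two-class sequence generator, and a command-line interface for
    training, prediction and proteome scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
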