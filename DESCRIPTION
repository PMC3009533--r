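Package: pulearn
Title: Positive-Unlabeled Learning for Sequence-Based Protein
    Classification
Version: 1.0.0
Authors@R:
    person("P.", "Reyes", email = "preyes@example.org",
           role = c("aut", "cre"))
Description: Implements a positive-unlabeled (PU) learning protocol for
    identifying membrane-binding peripheral protein domains from amino-acid
    sequence alone.  Reliable negative examples are mined from an unlabeled
    sequence pool with the spy technique (original and a modified
    fresh-spies-per-iteration variant), the negative set is expanded
    iteratively, and a final classifier is trained on the positive set
    versus the converged reliable-negative set.  Includes the sequence
    featurization the protocol runs on (net charge, hydrophobicity and
    secondary-structure propensity sums, amino-acid composition and a 4 x 20
    local-environment composition), an information-gain decision tree with
    Laplace-smoothed leaf probabilities, holdout and cross-validation
    evaluation, a synthetic two-population sequence benchmark generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
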