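Package: prosyn
Title: Prosody-Syntax Interaction Analysis and Cross-Condition Neural Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how prosodic boundary strength interacts with
    syntactic phrase closure in continuous speech, and how that interaction
    modulates the neural decodability of syntactic boundaries. Fits a
    two-component gamma mixture to word-level prosodic boundary strengths and
    binarizes them at the equal-posterior crossing; reads bracketed
    constituency trees and counts closing nodes per word; builds balanced
    neutral/coherent/incoherent generalization sets; extracts word-offset
    locked epochs from multichannel recordings with SVD dimensionality
    reduction; trains regularized logistic decoders with whole-window MVPA and
    per-timepoint temporal decoding; and runs group-level paired permutation
    tests, cluster-based permutation over time, and Bayesian population
    prevalence inference. A synthetic-data module generates multi-subject
    cohorts with a planted, condition-modulated signal so the full pipeline is
    testable without restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    glmnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'synth.R'
    'prosody.R'
    'syntax.R'
    'sets.R'
    'epochs.R'
    'logistic.R'
    'decode.R'
    'stats.R'
    'io.R'
    'pipeline.R'
    'prosyn-package.R'
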