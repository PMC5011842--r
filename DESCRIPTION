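Package: stagecast
Title: Stage Classification of Implementation Communication Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monitors the progress of multi-site program implementation from
    the free-text communication logs kept by implementation brokers.  Provides
    deidentification of log notes (names, phone numbers, email addresses), a
    Porter stemmer, max-relevance/min-redundancy keyword selection from stage
    description sentences, a semi-supervised non-negative matrix
    tri-factorization classifier that accepts partial note and keyword labels,
    and downstream temporal summaries: stage-probability trajectories with
    start/end date detection, stage-attainment flags, and Markov transition
    matrices.  Includes a synthetic-corpus generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
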