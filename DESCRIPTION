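Package: contrastinfo
Title: Contrast Information Dynamics for Discrete and Continuous Stochastic Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes contrast information, a coordinate-invariant dynamic
    information measure defined as the relative entropy from the conditional
    distribution of a target regime given a specific source observation and
    context to its distribution given the context alone. Provides the six
    temporal variants (predictive, connective, reflective and their backward
    counterparts), exact closed-form evaluation for stationary discrete- and
    continuous-time Markov chains and Gaussian processes, definitional
    brute-force and Monte-Carlo oracles, a variable-order PPM sequence model
    (escape method C, backoff smoothing, no update exclusion) producing
    per-event information-content, entropy and contrast profiles, model
    estimation from corpora, seeded simulators, and plain-text serialisation
    of models, event sequences and information profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
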