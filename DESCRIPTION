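Package: graphlearn
Title: Maximum-Entropy Learning of Transition Networks from Mental Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling how people learn the transition structure of
    stimulus sequences in serial-response experiments. Implements a
    maximum-entropy learner in which memory errors follow a Boltzmann
    distribution over temporal lags, its asymptotic closed-form transition
    estimate, per-subject reaction-time model fitting with grid search plus
    gradient refinement and BIC comparison against a hierarchy of
    higher-order transition models, n-back-based measurement of the memory
    distribution with bootstrap, generators for the modular, lattice and
    ring experiment graphs and their walk protocols, and a synthetic-cohort
    simulator so the full pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
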