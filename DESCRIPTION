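Package: qpcog
Title: Quantum Probability Engine for Predictive Cognition Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and interrogating quantum-probability models
    of cognition in which top-down predictions and bottom-up evidence are
    complementary measurement contexts over a shared state space. Provides
    pure states, orthonormal measurement contexts, Born-rule probabilities
    for rays and unions of rays, Lueders-rule collapse, unitary basis
    changes, sequential measurement paths, question order effects,
    interference against the law of total probability, compatibility
    diagnostics that recover classical Bayesian conditioning in the
    commuting limit, a packaged two-outcome worked example, a seeded
    synthetic model generator, JSON/YAML model serialization, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
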