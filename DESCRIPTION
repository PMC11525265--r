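Package: mptagg
Title: Aggregation Invariance Diagnostics and Simulation for Multinomial Processing Tree Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying aggregation invariance of multinomial processing
    tree (MPT) models: parsing and evaluation of EQN-style model definitions,
    structural (SAI) and weak empirical (WEAI) aggregation-invariance
    diagnostics, mechanical transformation of SAI-violating models, a
    latent-trait simulator with probit-scale moment matching, maximum-likelihood
    fitting of aggregated categorical frequency data, likelihood-ratio G-squared
    goodness-of-fit tests (aggregate, per-participant sum, and parametric
    bootstrap), exact population-level aggregation bias by Gauss-Hermite
    quadrature, and a factorial Monte Carlo experiment runner with seeded,
    scheduling-independent replication.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
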