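Package: tdrp
Title: Time-Dependent Substitution Rate Decay Models for Divergence Dating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for describing and correcting the time-dependent rate
    phenomenon (TDRP) in molecular evolution: the empirical observation that
    substitution-rate estimates decay continuously as the timescale over which
    they are measured increases. Implements four empirical rate-decay models
    (simple and vertically-translated exponential and power-law), fits them to
    node-dated phylogenetic data by nonlinear least squares under either an
    average-rate or a time-prediction criterion, compares them by leave-one-out
    cross-validation with Friedman and Wilcoxon signed-rank tests, and applies
    the winning model to recover short- and long-term rates and to infer
    unknown divergence dates. Includes a synthetic-data generator emulating a
    virus-host cospeciation dataset so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
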