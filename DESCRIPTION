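Package: musevol
Title: Statistical Models of Cultural Evolution in Music Styles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of transmitted cultural traits,
    with symbolic music as the worked case. Implements the statistical
    creator-evaluator (SCE) model, an iterated-learning dynamical system in
    which a beta-distributed feature frequency evolves under novelty and
    typicality selection followed by moment-matched learning, together with
    the closed-form log-potential comparison model. Provides feature
    extractors for symbolic music corpora (pitch-class-interval sequences,
    tritone and non-diatonic-motion frequencies, interval bigram
    probabilities, rare-rhythm frequencies), sliding-window corpus
    statistics with per-era beta fits, least-squares fitting of selection
    coefficients to observed mean/SD trajectories with forecasting, and a
    synthetic-corpus generator so the full pipeline can be exercised and
    validated without access to copyrighted corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
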