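Package: markovmemory
Title: Markov Chain Order Selection for Categorical Path Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits discrete Markov chains of arbitrary order to corpora of
    categorical paths (clickstreams, navigation sessions, symbolic event
    sequences) and determines the appropriate memory length via four
    complementary model-selection frameworks: nested likelihood-ratio
    testing with chi-squared calibration, Bayesian model comparison based
    on the closed-form Dirichlet-multinomial marginal likelihood, the AIC
    and BIC information criteria, and stratified cross-validated
    next-state prediction rank. Includes readers for delimited path files
    and the UCI MSNBC sequence format, RESET-boundary augmentation,
    Laplace/Dirichlet smoothing, synthetic corpus generators with known
    transition structure, and structural transition analyses
    (globally-normalised transition tables, top-transition extraction,
    self-transition profiles, endpoint-conditioned splits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
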