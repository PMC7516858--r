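Package: confirmr
Title: Confirmation Measures for 2x2 Evidence, Diagnostic Tests, and the Raven Paradox
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how strongly sample evidence supports an
    uncertain rule "if e then h". Implements the classical Bayesian
    confirmation measures (D, M, R, C, Z, S, N, L, F) and the certainty
    factor on 2x2 contingency counts, together with the channel confirmation
    measure b* (a monotone transform of the likelihood ratio) and the
    prediction confirmation measure c* (a transform of the correct rate)
    derived from semantic information theory. Includes probability
    prediction from degrees of confirmation, truth functions and semantic
    Bayes machinery, a maximum-mutual-information classifier, a medical-test
    evaluation and two-test decision engine (the NAT/CT COVID-19 use case),
    and a property lab that checks symmetry, monotonicity, normalization,
    logicality and the Nicod-Fisher criterion, including the raven-paradox
    increment experiment.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
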