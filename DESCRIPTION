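Package: ssbn
Title: Sons-and-Spouses Bayesian Networks for Discrete Health-Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised discrete Bayesian-network modelling for categorical
    survey cohorts with a rare binary outcome. Provides exact inference by
    variable elimination, Naive Bayes / Tree-Augmented Naive Bayes / Sons-and-
    Spouses structure learning, information-theoretic arc-strength and
    target-relevance metrics, Generalized Bayes Factor scoring with a
    genetic-algorithm search for the most relevant explanation of a target
    state, what-if posterior queries, stratified cross-validated evaluation,
    and a calibrated synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
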