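Package: mcdecide
Title: Metacognitive Control of Decisions: Trading Mental Effort for Confidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the metacognitive control of decisions (MCD) model,
    in which the amount of cognitive resources allocated to a value-based
    decision maximizes a tradeoff between weighted expected choice confidence
    and effort cost. From pre-choice value ratings and value-certainty
    ratings, the model predicts six trial-level behavioral variables:
    response time, subjective effort, choice confidence, change of mind,
    choice-induced spreading of alternatives, and value-certainty gain.
    Provides the closed-form belief-update and folded-normal confidence
    machinery, a numeric resource-allocation optimizer, a generative
    simulator of the full two-alternative rating/choice experiment,
    per-subject MAP + Laplace parameter estimation with out-of-sample
    prediction and parameter recovery, the standard model-free analyses
    (within-subject standardized regressions, group-level random-effects
    tests, median splits), and permutation-based chance levels for
    prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
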