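Package: dreadr
Title: Dread-Discounting Models of Intertemporal Choice Over Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, simulation and inference tools for intertemporal choice
    over aversive outcomes. Implements a family of value models for delayed
    pain in which anticipatory disutility (dread) accumulates during the
    delay, a softmax choice likelihood, bounded multistart maximum-likelihood
    fitting with grid-search verification, BIC-based fixed-effects model
    comparison, a framing-effect parameter-restriction battery, model-free
    choice-curve summaries with phenotype classification, and synthetic-cohort
    generators that emulate an interleaved shock-choice task and a
    hypothetical dental-appointment task with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
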