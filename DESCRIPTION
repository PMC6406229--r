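Package: lexlit
Title: Dynamic Word-Recognition Health Literacy Tests with Item-Weighted
    Kappa Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds word-recognition (Yes-No vocabulary) health literacy
    instruments on the fly from any word-frequency corpus: the vocabulary
    is filtered against a reference lexicon, partitioned into frequency
    tiers, true words are sampled per tier and pronounceable pseudowords
    are generated from tier templates via a subsyllabic transition chain.
    Respondents answer on a 4-level Likert scale and are scored against a
    master key with an item-weighted generalization of weighted Cohen's
    kappa, where item weights are a logistic transform of standardized
    log word frequency. Includes a graded-response simulation suite for
    in-silico reliability and validity experiments, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
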