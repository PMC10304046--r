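Package: suppuse
Title: Detecting Dietary Supplement Use in Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A natural language processing pipeline for detecting active
    dietary supplement use in free-text and semi-structured clinical notes.
    A keyword lexicon drives extraction of +/-20-token snippets around each
    supplement mention; a linear support vector machine over binary bigram
    features plus a keyword indicator classifies each mention as active use
    or not; document-level predictions are rolled up to per-patient,
    per-category calls within a survey-anchored date window; and agreement
    with self-reported survey data is summarised with per-category confusion
    matrices and micro/macro precision, recall and F1. A synthetic note and
    survey generator with known ground truth and controllable self-report
    discordance supports evaluation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
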