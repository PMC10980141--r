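Package: stbhistory
Title: Detect Personal and Family History of Suicidal Thoughts and
    Behaviors in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects documented personal and family history of suicidal
    thoughts and behaviors (suicidal ideation, suicidal behavior, suicide
    attempt) in free-text clinical notes.  Provides a lexicon-driven rule
    engine with ConText-style negation and kinship-proximity family
    attribution, document-level label aggregation by majority polling with
    a last-mention tie break, an anchor/context-window span pipeline
    feeding a seeded cross-validated text classifier, evaluation utilities
    (per-class/macro/weighted precision-recall-F1, Cohen's kappa, an ICD
    diagnosis-code baseline comparison), readers and writers for JSONL
    corpora and BRAT standoff annotations, and a seeded synthetic note
    generator with instance-level ground truth so the whole pipeline can
    be exercised and benchmarked without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
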