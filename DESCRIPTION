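Package: epiletter
Title: Language-Model Classification of First-Visit Paediatric Seizure Letters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to classify free-text anamnesis letters from paediatric
    first seizure clinic consultations as 'epilepsy' or 'no epilepsy'.
    Implements two arms: a multinomial Naive Bayes classifier over n-gram
    TF-IDF features selected by recursive feature elimination with
    cross-validation, and a sentence-embedding arm (offline seeded
    hash-projection provider) feeding a boosted linear classifier.
    Includes stratified train/test splitting, diagnostic-accuracy metrics
    with exact binomial confidence intervals, McNemar paired-model
    comparison, and a seeded synthetic letter generator with known
    generative parameters so that every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    readr,
    stringr,
    stringi,
    tibble,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
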