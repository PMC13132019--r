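Package: qolforum
Title: Concordance Between Quality-of-Life Annotations in Patient Forum
    Posts and EORTC Questionnaire Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how well quality-of-life (QoL) information
    annotated in patients' online forum posts predicts their answers to the
    EORTC QLQ-C30 and QLQ-BR23 questionnaires. Provides a data model and
    plain-text I/O for forum documents, span annotations and survey records;
    dual-granularity (word and document) inter-annotator agreement via Fleiss
    kappa; binarised annotation-survey concordance (precision, recall, F1)
    with fine and coarse question grouping and temporal filtering; EORTC
    0-100 scale scoring; and a seeded synthetic cohort generator with a
    latent-state model so every pipeline stage is testable without access to
    private study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
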