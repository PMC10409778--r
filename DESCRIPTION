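Package: cannascreen
Title: Screening and Classification of Cannabis-Use Documentation in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting cannabis-use documentation and
    positive use in unstructured clinical notes. Builds a cannabis-term lexicon
    and expands it with corpus-observed misspellings via character n-gram cosine
    similarity; screens notes for keyword mentions with context exclusions for
    false-positive senses (common bile duct, plant allergens) and an age filter;
    extracts keyword-anchored sentences; classifies sentences as positive or
    negative use with a deterministic negation-aware rule baseline and a
    trainable n-gram linear model; aggregates labels to patient-level status;
    computes yearly documentation and positivity trends; cross-checks detected
    patients against cannabis-related diagnostic codes (ICD-9-CM, ICD-10-CM,
    SNOMED CT); and estimates adjusted odds ratios for demographic and
    socioeconomic disparities. Includes a synthetic note-corpus generator with
    planted ground truth so every stage is testable without protected health
    information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    glmnet,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
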