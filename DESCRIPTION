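Package: amorchron
Title: Diachronic Salience of Romantic Love in Historical Play Texts
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for measuring the cultural salience of tender
    versus passionate love in historical theatre corpora and relating it
    to annual living-standards and demographic series. Plays are reduced
    to spoken text, normalized and lemmatized, and scored by counting
    curated category words inside short windows around love-related seed
    words; a per-play romantic-love score is the difference of z-scored
    tender and passionate category frequencies. The package includes
    lexicon curation tools (candidate extraction near seeds, count-based
    word embeddings with nearest-neighbour audits and a majority
    retention rule), internal validation by maximum-likelihood factor
    analysis, external validation against user-supplied dictionary
    categories, mixed-effects models with author as a random factor,
    cross-correlation, lagged regression with backward BIC selection and
    a generalized least squares refit under AR(1) errors, and synthetic
    corpus and time-series generators with recorded ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    nlme,
    MASS,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
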