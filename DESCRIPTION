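Package: methrisk
Title: Methylation-Based Mortality Risk Scores, Epigenetic Age
    Acceleration and Frailty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs and compares blood DNA-methylation survival
    indicators in population cohorts of older adults: a 10-CpG
    mortality risk score in count-based (MRscore) and weighted
    continuous (cont.MRscore) form, epigenetic age acceleration
    (residual of DNA-methylation age on chronological age), and a
    deficit-accumulation frailty index.  Provides probe filtering,
    deficit screening and chained-equation multiple imputation,
    batch-random-effect linear models with Rubin pooling and
    Benjamini-Hochberg correction, Cox and Barlow-weighted case-cohort
    survival models, logistic models for nested case-control samples,
    DerSimonian-Laird random-effects meta-analysis, and predictive
    accuracy metrics (Harrell's C, IPCW Brier prediction-error curves,
    time-dependent AUC).  A calibrated synthetic-cohort generator
    emulates the joint structure of methylation scores, frailty and
    mortality so every stage is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    lme4,
    metafor
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
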