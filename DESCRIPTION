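Package: sesagree
Title: Agreement Between Subjective and Objective Socioeconomic Status Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing a subjective socioeconomic status (SES)
    measure, the 10-rung MacArthur ladder self-rating, with the WAMI, a
    composite objective SES index built from improved water and sanitation,
    a PCA-based household asset score, education years, and monthly income.
    Provides WAMI score construction from raw survey responses, ordinal
    rescaling of both scores onto common 3/4/5/10-category scales,
    agreement statistics (Spearman rank correlation, Fleiss-Cohen
    quadratic-weighted kappa with Landis-Koch interpretation, Bland-Altman
    percentile outlier detection), a retest-substitution analysis that
    quantifies how replacing initial ladder reports with retest reports
    changes agreement, age- and gender-adjusted logistic outcome models
    compared by AIC, and a calibrated synthetic-cohort generator with
    configurable subjective-reporting error channels (scale reversal,
    heaping on the middle rung) so the whole pipeline is testable without
    access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
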