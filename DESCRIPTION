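Package: endoprs
Title: Polygenic Risk, Comorbidity Burden, and Their Interaction in
    Endometriosis Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how polygenic risk for endometriosis
    interacts with diagnosed comorbidities in biobank-style case-control
    cohorts. Provides a multi-trait liability-threshold simulator with
    shared genetic and non-genetic factors, ICD-10-style code
    normalization and chapter-aware comorbidity-burden metrics,
    phenome-wide per-code association scanning with false-discovery-rate
    control, polygenic-score standardization and quantile stratification
    (centile odds ratios, AUC), and additive- and multiplicative-scale
    interaction models between polygenic score and comorbidity status,
    wired together by a deterministic cross-cohort pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
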