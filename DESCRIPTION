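Package: mashdx
Title: Non-Invasive MASH Diagnosis from Liver 1H-MR Spectroscopy and Clinical Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates liver 1H-MR spectra and transplant-cohort clinical data,
    quantifies liver fat fraction and fatty-acid unsaturation indices by
    linear-combination fitting with T2 correction, screens candidate biomarkers
    of metabolic dysfunction-associated steatohepatitis (MASH) by ROC analysis
    with Youden-optimal cut-offs, classifies MASH with a recursive-partitioning
    decision tree scored by the G2 likelihood-ratio statistic and pruned by
    LogWorth, and reports prevalence-adjusted diagnostic accuracy and positive
    predictive value. Includes a synthetic cohort generator calibrated to
    published group summaries (log-normal/normal marginals solved from medians
    and quartiles, Gaussian-copula dependence), group-comparison statistics,
    stepwise logistic confirmation, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
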