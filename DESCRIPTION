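Package: musclemeta
Title: Multi-Cohort Meta-Analysis of Age-Related Muscle Methylation and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying age-related DNA
    methylation and gene expression features in skeletal muscle across many
    cohorts, and for quantifying how cardiorespiratory fitness, exercise
    training, and disuse shift those features. Provides per-cohort
    epigenome-/transcriptome-wide association fits, random-effects
    meta-analysis with an empirical-Bayes (Paule-Mandel) between-cohort
    heterogeneity estimator, probe-count-bias-adjusted gene-set
    over-representation (Wallenius noncentral hypergeometric), signed
    -log10(p) importance scores with rank-MANOVA multi-contrast enrichment,
    cross-contrast effect-size correlation and Q-Q inflation diagnostics, and
    a synthetic multi-cohort data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
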