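Package: pdxresponse
Title: Drug Response Analysis for Patient-Derived Xenograft Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to analyse repeated tumor-volume measurements from
    patient-derived xenograft (PDX) preclinical trials. Supports the four
    common trial designs (single or multiple tumors, arms, and animals per
    arm), between-arm statistics on endpoint volumes and growth rates
    (one-way ANOVA, Kruskal-Wallis, Scheirer-Ray-Hare, mixed-design ANOVA,
    linear mixed models, and a growth-curve permutation test), tumor growth
    inhibition (TGI) under difference, ratio and AUC functionals,
    animal-level response labeling under three published standards with
    arm-level response rate and disease control rate, a synthetic-trial
    simulator with known ground truth, and publication-style figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
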