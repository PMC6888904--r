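Package: vatclock
Title: Epigenetic Age Acceleration in Visceral Adipose Tissue and Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores DNA-methylation (DNAm) age from Illumina 450k/EPIC
    beta-value matrices with a coefficient-defined epigenetic clock (including
    the nonlinear age calibration and reduced-CpG clock construction), computes
    epigenetic age acceleration as the residual of DNAm age regressed on
    chronological age, and runs the downstream association analyses for
    severe-obesity cohorts: Pearson correlation with BMI, correlation power
    analysis via the Fisher z transformation, multivariate linear models with
    confidence intervals, sex-stratified and age-trimmed subgroup analyses,
    percent excess-body-weight-loss (%EBWL) trajectory clustering after
    bariatric surgery (summary measures, factor-based selection of
    nonredundant measures, k-means with Calinski-Harabasz model selection),
    and binomial logistic trend models linking adjusted acceleration to
    weight-loss trajectory groups and metabolic syndrome. A synthetic-cohort
    generator with a generative inversion of the clock makes every stage
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
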