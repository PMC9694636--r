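Package: ghdpgs
Title: Polygenic Risk Scores for Gestational Hypertensive Disorders
Version: 0.1.0
Authors@R: person("GHD PGS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for building and evaluating polygenic risk
    scores (PGS) for gestational hypertensive disorders from case-control
    genotype data: synthetic cohort simulation with LD-structured genotypes
    and a known generative disease model, ICD-10-style case/control cohort
    definition, p-value SNP selection and greedy LD clumping, balanced-
    resampling logistic PGS training with repeated cross-validated AUC model
    selection and a forward-AIC variant, percentile-based odds-ratio risk
    stratification with Wald intervals, BMI-band by PGS-septile odds-ratio
    grids, and two-sample Mendelian randomization (IVW and MR-Egger with a
    pleiotropy intercept test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
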