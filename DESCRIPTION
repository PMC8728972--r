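Package: gdmpanel
Title: Multivariate Longitudinal Discriminant Analysis of Early-Pregnancy
    Blood Biomarkers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for early prediction of gestational diabetes mellitus
    (GDM) from repeated first- and early-second-trimester measurements of
    hemoglobin, hematocrit, fasting blood sugar and red blood cell count.
    Implements a multivariate longitudinal linear mixed model with
    subject-level random intercepts, a two-population linear discriminant
    allocation rule with prior-proportion threshold, ROC/AUC evaluation
    (Mann-Whitney estimator, DeLong and bootstrap confidence intervals),
    two-step 50-g glucose load / 100-g OGTT screening by Carpenter-Coustan
    criteria, group-comparison descriptives (t, chi-square, mixed-design
    repeated-measures ANOVA), and a seeded synthetic-cohort generator
    calibrated to published summary statistics so the full analysis
    pipeline is reproducible without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
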