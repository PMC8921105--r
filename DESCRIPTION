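Package: mpMRIgrade
Title: MRI Grading Groups for Prostate Cancer Aggressiveness
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deterministic implementation of a three-tier MRI grading system
    (mG1-mG3) that combines quantitative diffusion (ADC thresholds per DWI
    technique), high b-value signal, T2 conspicuity, cross-zonal growth and
    extraprostatic extension to stratify prostate cancer aggressiveness
    against biopsy ISUP grade groups. Ships the published grade-by-ISUP
    cross-tabulation as a packaged fixture, computes per-grade risks of
    ISUP >= 2 and >= 3 with Wilson score intervals, provides tie-corrected
    Kendall tau-b (vector and cell-weighted contingency-table forms),
    Spearman correlation on midranks, one-way ANOVA with Bonferroni
    correction and a multivariable linear predictor of ISUP grade, and
    includes a seeded synthetic cohort generator calibrated to the published
    per-ISUP summary statistics so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
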