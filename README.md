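# mpMRIgrade

Prediction of prostate-cancer aggressiveness from multiparametric MRI
(mpMRI) with a deterministic three-tier **MRI grading system (mG1–mG3)**,
together with the statistics needed to evaluate such a system against
biopsy ISUP grade groups and a seeded synthetic cohort generator that makes
the whole pipeline testable without patient-level data.

The package is aimed at radiologists and biostatisticians working on
MRI-based risk stratification: PI-RADS estimates the *likelihood* of
clinically significant cancer; the grading rule implemented here targets
the complementary question of how *aggressive* a biopsy-confirmed cancer is
likely to be, which drives decisions such as early re-biopsy versus active
surveillance.

## The grading rule

Each MRI-visible index lesion is described by its apparent diffusion
coefficient (ADC, µm²/s) with the DWI readout technique (readout-segmented
`rs_epi` vs single-shot `ss_epi`, whose ADC scales differ by ~100 µm²/s),
hyperintensity on calculated b1800 images, T2 conspicuity (*discreet* <
*overlayed* < *clear*), cross-zonal growth, and extraprostatic extension
(EPE / cT3). The rule assigns exactly one grade, most aggressive rule
first:

* **mG3** — EPE present, **or** ADC < 900 (rs-EPI) / < 800 (ss-EPI) **and**
  high-b hyperintense **and** clear T2 lesion;
* **mG1** — otherwise, if ADC > 900 (rs-EPI) / > 800 (ss-EPI) **and**
  discreet T2 **and** no cross-zonal growth **and** no EPE;
* **mG2** — everything else.

All comparisons are strict, thresholds are re-calibratable per institution
(`GradingThresholds()`), and the rule is total and monotone: lowering ADC
or raising T2 conspicuity never lowers the grade.

## Worked example

```r
library(mpMRIgrade)

## the packaged study cross-tabulation: 187 graded lesions
table3CrossTab()
#> ISUP x MRI-grade cross-tabulation (187 graded lesions)
#>       mG1 mG2 mG3 All
#> ISUP1  17  20   3  40
#> ISUP2  10  24  13  47
#> ISUP3   4  20  26  50
#> ISUP4   0  14  36  50
#> All: 31 / 78 / 78

riskTable(table3CrossTab())
#> Risk of ISUP >= 2 / >= 3 per MRI grading group (Wilson 95% CI)
#>      n     risk_ge2     risk_ge3
#> mG1 31 45% (29-62%) 13% ( 5-29%)
#> mG2 78 74% (64-83%) 44% (33-55%)
#> mG3 78 96% (89-99%) 79% (69-87%)

kendallTauBFromTable(table3CrossTab())
#> kendall_tau_b = 0.4752 (n = 187, p = 9.56e-14)

## grade a single lesion
classifyLesion(list(dwi_technique = "rs_epi", adc_um2_s = 704,
                    high_b_hyperintense = 1, t2_conspicuity = "clear",
                    cross_zonal = 1, epe = 0))
#> [1] 3
```

Reading the risk table: of the 31 mG1 lesions, 45% harboured clinically
significant cancer (ISUP ≥ 2) and only 13% high-grade cancer (ISUP ≥ 3),
against 96% and 79% in mG3 — the gradient that motivates early re-biopsy
for low-grade biopsy results in mG3 lesions. The tau-b of 0.48 quantifies
the ordinal association between grading group and ISUP group over the 187
graded lesions.

The full pipeline runs on synthetic cohorts drawn from the packaged
per-ISUP calibration (50 patients per grade group below, as in the study
design):

```r
report <- runAnalysis(generateCohort(n = 50, seed = 7))
riskGe2(report@riskTable)
#>       mG1       mG2       mG3
#> 0.3000000 0.7647059 0.9696970
```

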