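---
title: "MRI grading of prostate cancer aggressiveness: model, calibration and design notes"
author: "mpMRIgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI grading of prostate cancer aggressiveness: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpMRIgrade)
```

## The problem

Biopsy ISUP grade groups (1–5; here 4 and 5 merged into a combined level 4)
order prostate cancers by histopathologic aggressiveness. PI-RADS scores the
likelihood that a lesion is clinically significant (ISUP ≥ 2), but it is not
designed to grade *how* aggressive a confirmed cancer is. The MRI grading
system implemented here (mG1–mG3) combines quantitative diffusion and
qualitative morphologic descriptors into an ordinal pre-biopsy estimate of
aggressiveness, intended to complement PI-RADS — for example to prompt an
early re-biopsy when a highly suspicious (mG3) lesion returns a negative or
low-grade biopsy, or to support primary surveillance for mG1 lesions.

## The grading rule

A visible index lesion is described by six features: DWI readout technique
(`rs_epi` or `ss_epi`; readout-segmented DWI yields systematically higher
ADC than single-shot, hence technique-specific cut-offs 100 µm²/s apart),
ADC in µm²/s, hyperintensity on calculated b1800 images (0/1), T2
conspicuity (ordinal *discreet* < *overlayed* < *clear*), cross-zonal
growth (0/1) and extraprostatic extension (EPE/cT3, 0/1).

`classifyLesion()` evaluates the rows most-aggressive-first:

1. **mG3** iff `epe == 1` **or** (ADC `<` 900 rs-EPI / 800 ss-EPI **and**
   `high_b == 1` **and** T2 `== "clear"`);
2. else **mG1** iff ADC `>` 900 rs-EPI / 800 ss-EPI **and** T2
   `== "discreet"` **and** `cross_zonal == 0` **and** `epe == 0`;
3. else **mG2**.

Three design points deserve comment, because the published rule table is
ambiguous on them:

* **Overlapping ADC bands.** An rs-EPI ADC of 950 µm²/s satisfies both the
  mG1 condition (`> 900`) and the mG2 condition (`< 1000`). The precedence
  mG3 → mG1 → mG2 resolves every overlap deterministically: the most
  aggressive satisfied rule wins, then the most benign, and mG2 is the
  residual class. This ordering is what makes the rule total and gives it
  the monotonicity properties below.
* **The mG3 connector.** The rule table's connector between the DWI block
  and the T2 block of the mG3 column can be read as a conjunction
  (low ADC ∧ high-b ∧ clear T2, with EPE as the only disjunct) or as
  allowing a clearly conspicuous T2 lesion alone to qualify. The package
  defaults to the conjunctive reading and exposes the alternative behind
  `mg3T2Alone = TRUE` rather than guessing a single intent. Both readings
  keep EPE dominance and monotonicity.
* **Boundary ADC values.** The printed cut-offs use strict comparison
  signs, so a lesion exactly at a threshold fails that row and falls
  through (e.g. rs-EPI ADC = 900 is neither "> 900" nor "< 900"; if its T2
  is discreet and it is organ-confined and unifocal it grades mG2, the
  residual). How boundary lesions were graded in the source study is not
  stated; strictness is the only reading consistent with the printed signs.

The rule satisfies, and the test suite sweeps (10⁴ random feature vectors
per property), four invariants: totality; EPE ⇒ mG3 regardless of all other
features; decreasing ADC never decreases the grade; increasing T2
conspicuity never decreases the grade. The rs-EPI and ss-EPI rules coincide
exactly after shifting ADC by the 100 µm²/s threshold difference.
Thresholds are a `GradingThresholds` object, so other institutions can
re-calibrate without touching the rule; validity enforces
`mg3Max ≤ mg1Min < mg2Max` per technique.

```{r rule}
GradingThresholds()
classifyLesion(list(dwi_technique = "rs_epi", adc_um2_s = 950,
                    high_b_hyperintense = 1, t2_conspicuity = "overlayed",
                    cross_zonal = 0, epe = 0))
```

## The packaged cross-tabulation and the risk table

The published study graded 187 of 200 biopsy-confirmed cancers (13 were
invisible on mpMRI: 10 ISUP 1, 3 ISUP 2). Its grade-by-ISUP
cross-tabulation ships as a read-only fixture with asserted marginals
(rows 40/47/50/50, columns 31/78/78):

```{r fixture}
table3CrossTab()
riskTable(table3CrossTab())
```

Risks are column-conditional proportions; the displayed percents use
half-up rounding (centralized in the package), under which 62/78 = 79.49%
prints as 79 — the source study printed 80%, a rounding discrepancy
`reproducePaper()` flags as *known* rather than as a failure. Confidence
intervals are Wilson score intervals, chosen over Wald for their behaviour
at small n and extreme proportions (the mG3/ISUP ≥ 2 cell is 75/78); the
study itself printed no intervals, so these are an addition, not a
reproduction.

## Association statistics

`kendallTauB()` implements tie-corrected tau-b,
τ_b = (C − D) / √((n₀ − n₁)(n₀ − n₂)), counting pairs on the contingency
table in O(rows × cols) via 2-D prefix sums; `kendallTauBFromTable()` is
the same computation on a `CrossTab` and agrees *exactly* with the vector
form on expanded labels (an equivalence the tests check against an O(n²)
brute-force pair enumeration on random tables). p values use the normal
approximation with the standard tie-corrected variance of S and are
documented as approximate. `spearmanRho()` is the Pearson correlation of
midranks with a t-approximation p value. `oneWayAnova()` is the classical
fixed-effects F; `bonferroniAdjust()` applies m·p clamping.

On the fixture, τ_b = 0.475 and Spearman ρ = 0.540. The source study prints
τ = 0.534 for the grading group; that value is reproducible from its counts
under neither statistic (its handling of the 13 invisible lesions is not
specified, and its text attributes the correlations to Kendall while the
corresponding table caption says Spearman). The package therefore reports
both statistics and does not target 0.534.

```{r tau}
kendallTauBFromTable(table3CrossTab())
```

`linearModelFit()` is the multivariable predictor of the ISUP level on
rs-EPI lesions (cross-zonal growth, EPE, high-b signal, ADC, grading group
with mG3 as reference). The source study fitted a linear mixed model by
REML "to account for within-patient correlations", but with exactly one
index lesion per patient there is no within-patient replication and no
random effect is identifiable — the fixed-effects least-squares fit *is*
the model. The package deliberately implements ordinary least squares with
normal-theory 95% intervals and records this in every JSON report; REML
variance components are out of scope. Designs are checked for rank
deficiency (aliased terms are reported by name) and for n > #parameters.

## The synthetic cohort generator

No patient-level data were deposited, so `generateCohort()` draws cohorts
whose per-ISUP marginals reproduce the published summary statistics,
making every downstream stage testable. Per ISUP group (n patients each,
mirroring the 50-per-group study design):

* **age** — normal with the published mean/SD, truncated to 40–95 years by
  inverse-CDF sampling;
* **PSA, PSA density, biopsy infiltration (clipped to 1–100%), lesion
  diameter, ADC** — lognormal, parameterized from the published
  "median (IQR)" by `lognormalFromMedianIQR()`: µ = log(median) (median
  exact by construction) and σ the average of the two one-sided quartile
  estimates, σ = [log(q₃/median) + log(median/q₁)] / (2 · z₀.₇₅). For
  asymmetric printed IQRs (e.g. PSA 11.6 [6.6–15.2] in the highest grade
  group) a two-parameter lognormal cannot hit both quartiles; the averaged
  σ splits the error between them, so sampled quartiles match the *fitted*
  distribution, not the printed quartiles, to within Monte-Carlo error.
  The tests assert exactly that;
* **prostate volume** — derived as PSA / PSAD rather than sampled, which
  keeps the PSAD ≡ PSA/volume invariant exact to machine precision and
  yields a median volume near 44 ml, a realistic figure; the study never
  prints a volume distribution;
* **visibility, cross-zonal growth, cT3, high-b positivity** — Bernoulli
  with the published per-group prevalences (e.g. visibility 0.80, 0.94,
  0.98, 1.00);
* **zone** — categorical from the published per-zone lesion counts divided
  by the group size of 50 (the printed counts sum to 50 per group even
  though fewer lesions were visible in the low-grade groups — an
  inconsistency of the source; zone is only emitted for visible lesions);
* **DWI technique** — rs-EPI with probability 0.40 per patient, and the
  lesion's ADC is drawn from the technique-matching distribution of its
  group. The source reports 125 ss-EPI and 96 rs-EPI acquisitions in 200
  patients (summing to 221, so some patients had both); the simulator does
  not model dual acquisitions;
* **T2 conspicuity and PI-RADS** — categorical with per-group probability
  triples that the source does not print anywhere. The defaults
  (T2 discreet/overlayed/clear = 0.70/0.25/0.05, 0.40/0.35/0.25,
  0.20/0.30/0.50, 0.05/0.20/0.75; PI-RADS 3/4/5 = 0.45/0.45/0.10,
  0.25/0.50/0.25, 0.15/0.45/0.40, 0.05/0.35/0.60) are **invented
  calibration knobs**: monotone in ISUP and chosen once so that the
  simulated grade distribution is qualitatively close to the published
  cross-tabulation. They are overridable through the `CohortConfig`.

Features are sampled conditionally independent given the ISUP group
(beyond the technique→ADC link). This is the simulator's main
simplification: real lesions correlate ADC with T2 conspicuity, high-b
signal, EPE and size, so the synthetic joint distribution is flatter than
reality. Consequently, passing tests demonstrate calibration of the
*marginals* and the qualitative risk gradient (risk of ISUP ≥ 2 rising
strictly across mG1 → mG2 → mG3), not patient-level exchangeability with
the study cohort; published patient-level statistics such as τ = 0.534 are
not reproduction targets.

Reproducibility: one seed per `generateCohort()` call; each ISUP group
draws from its own substream derived deterministically from the seed, and
the caller's RNG state is restored afterwards. Identical (config, n, seed)
give byte-identical CSVs.

```{r cohort}
co <- generateCohort(n = 50, seed = 7)
report <- runAnalysis(co)
riskGe2(report@riskTable)
```

## Numerical choices

* Pair counting for tau-b is the O(rows × cols) cell-weighted form —
  cohort sizes here never justify the O(n log n) sort-based algorithm —
  validated against brute-force enumeration.
* Display rounding is half-up to integer percent (`79.5 → 80`), matching
  how the published percentages read off the fixture fractions, and is
  centralized so reports cannot disagree.
* ADC is µm²/s (= 10⁻⁶ mm²/s) everywhere. The published summary table
  header says "× 10⁻³ mm²/s", which is treated as a typographical slip:
  printed values of 600–1100 are physiological only on the 10⁻⁶ mm²/s
  scale. CSV headers name the unit (`adc_um2_s`).
* ISUP 5 input labels are accepted and merged into the combined level 4
  with a message; ordinal codes are 1 < 2 < 3 < 4 throughout.
* Degenerate inputs fail loudly: constant vectors make tau/rho an
  explicit undefined-statistic error (never a silent 0), empty grading
  columns name the grade, rank-deficient designs name the aliased terms,
  cohort schema violations name the rule and the first offending rows.

## Problem sizes in the test suite

The suite runs at sizes chosen to separate signal from Monte-Carlo noise
while staying quick: distribution recovery at 10⁵ patients per group
(medians within 3%, prevalences within 1 point), rule properties over 10⁴
random feature vectors, tau-b equivalence over 100 random tables, risk
gradients and ordering over 100 seeded cohorts of 200 per group,
linear-model interval coverage over 200 replicates of n = 2000 (per
coefficient ≥ 93%), and calibration spot-checks at 5000 per group (PSA and
ADC medians within 5%, visibility within 2 points). The ANOVA power check
uses the published age means/SDs at 50 per group, where the noncentral-F
power is 0.92 at α = 0.05 (and 0.54 at α = 0.001, which the empirical rate
matches).

## Known limitations

* The generator reproduces marginals, not joint structure; effect sizes of
  multivariable fits on synthetic data are not comparable to the published
  coefficients.
* tau-b p values are asymptotic; at very small n an exact permutation test
  would be preferable.
* The grading engine consumes tabular features only. Image analysis — ROI
  placement, PI-RADS scoring, diameter measurement — is explicitly out of
  scope, as are biopsy procedure, PRECISE follow-up criteria and
  prostatectomy outcomes.
* Thresholds were defined for a specific scanner/protocol family;
  re-calibration is expected before use elsewhere, which is why they are
  first-class objects rather than constants.
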