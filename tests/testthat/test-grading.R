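baseLesion <- function(...) {
  f <- list(dwi_technique = "rs_epi", adc_um2_s = 950,
            high_b_hyperintense = 1, t2_conspicuity = "overlayed",
            cross_zonal = 0, epe = 0)
  utils::modifyList(f, list(...))
}

test_that("ADC criteria use strict technique-specific thresholds", {
  expect_true(adcMeets(1, "rs_epi", 901))
  expect_false(adcMeets(1, "rs_epi", 900))   # boundary fails strict >
  expect_false(adcMeets(3, "ss_epi", 800))   # boundary fails strict <
  expect_true(adcMeets(3, "ss_epi", 799))
  expect_true(adcMeets(2, "rs_epi", 999))
  expect_false(adcMeets(2, "rs_epi", 1000))
  expect_error(adcMeets(1, "dti", 900), "unknown DWI technique")
  expect_error(adcMeets(1, "rs_epi", -5), "positive")
})

test_that("the grading rule reproduces the documented example lesions", {
  # extraprostatic extension alone forces mG3
  expect_identical(classifyLesion(baseLesion(epe = 1, adc_um2_s = 2000,
                                             t2_conspicuity = "discreet")),
                   3L)
  # high ADC, discreet T2, organ-confined, unifocal: mG1
  expect_identical(classifyLesion(baseLesion(adc_um2_s = 1100,
                                             high_b_hyperintense = 0,
                                             t2_conspicuity = "discreet")),
                   1L)
  # marked ADC reduction + high-b signal + clear T2: mG3
  expect_identical(classifyLesion(baseLesion(adc_um2_s = 704,
                                             t2_conspicuity = "clear",
                                             cross_zonal = 1)),
                   3L)
  # mG3 fails (T2 not clear), mG1 fails (T2 not discreet): residual mG2
  expect_identical(classifyLesion(baseLesion()), 2L)
  expect_error(classifyLesion(baseLesion(adc_um2_s = NULL)),
               "adc_um2_s")
})

test_that("the alternative mG3 connector reading is switchable", {
  clearOnly <- baseLesion(adc_um2_s = 1100, high_b_hyperintense = 0,
                          t2_conspicuity = "clear")
  expect_identical(classifyLesion(clearOnly), 2L)
  expect_identical(classifyLesion(clearOnly, mg3T2Alone = TRUE), 3L)
})

test_that("cohort classification conserves counts and flags invisible cancers", {
  co <- generateCohort(n = 30, seed = 21)
  lab <- classifyCohort(co)
  expect_identical(lab$patient_id, co$patient_id)  # output order = input
  expect_identical(sum(lab$mGrade == "not_visible"), sum(co$visible == 0))
  expect_true(all(lab$mGrade[co$visible == 1] %in% paste0("mG", 1:3)))

  expect_identical(nrow(classifyCohort(co[0, ])), 0L)

  allEpe <- randomLesionCohort(50)
  allEpe$epe <- 1L
  expect_true(all(classifyCohort(allEpe)$mGrade == "mG3"))

  dup <- co[c(1, 1), ]
  expect_error(classifyCohort(dup), "duplicate patient_id")
})

test_that("cross-tabulation counts label pairs and merges ISUP 5", {
  z <- crossTabFromLabels(integer(), integer())
  expect_identical(sum(counts(z)), 0L)
  one <- crossTabFromLabels(1, 1)
  expect_identical(counts(one)["ISUP1", "mG1"], 1L)
  expect_identical(sum(counts(one)), 1L)

  lab <- expandLabels(counts(table3CrossTab()))
  expect_identical(counts(crossTabFromLabels(lab$isup, lab$mg)),
                   counts(table3CrossTab()))

  expect_message(m5 <- crossTabFromLabels(c(4, 5), c(3, 3)), "ISUP 5")
  expect_identical(counts(m5)["ISUP4", "mG3"], 2L)
})

test_that("the rule is total and EPE-dominant over a random feature sweep", {
  set.seed(4201)
  sweep <- randomLesionCohort(10000)
  lab <- classifyCohort(sweep)
  expect_true(all(lab$mGrade %in% paste0("mG", 1:3)))       # totality
  expect_true(all(lab$mGrade[sweep$epe == 1] == "mG3"))     # EPE dominance
})

test_that("grades are monotone in ADC and T2 conspicuity", {
  set.seed(4202)
  base <- randomLesionCohort(2000)
  grid <- c(150, 450, 750, 799, 800, 801, 850, 899, 900, 901, 950, 999,
            1000, 1200, 2500)
  # decreasing ADC must never decrease the grade
  swept <- base[rep(seq_len(nrow(base)), each = length(grid)), ]
  swept$adc_um2_s <- rep(grid, times = nrow(base))
  swept$patient_id <- sprintf("S%07d", seq_len(nrow(swept)))
  g <- matrix(gradeCode(classifyCohort(swept)$mGrade),
              ncol = length(grid), byrow = TRUE)
  expect_true(all(g[, -1] <= g[, -length(grid)]))

  # increasing T2 conspicuity must never decrease the grade
  t2grid <- c("discreet", "overlayed", "clear")
  swept2 <- base[rep(seq_len(nrow(base)), each = 3), ]
  swept2$t2_conspicuity <- rep(t2grid, times = nrow(base))
  swept2$patient_id <- sprintf("T%07d", seq_len(nrow(swept2)))
  g2 <- matrix(gradeCode(classifyCohort(swept2)$mGrade), ncol = 3,
               byrow = TRUE)
  expect_true(all(g2[, 2] >= g2[, 1]))
  expect_true(all(g2[, 3] >= g2[, 2]))
})

test_that("rs-EPI and ss-EPI rules coincide after the 100 um2/s threshold shift", {
  set.seed(4203)
  rs <- randomLesionCohort(4000)
  rs$dwi_technique <- "rs_epi"
  ss <- rs
  ss$dwi_technique <- "ss_epi"
  ss$adc_um2_s <- rs$adc_um2_s - 100
  ss <- ss[ss$adc_um2_s > 0, ]
  rs <- rs[rs$adc_um2_s > 100, ]
  expect_identical(classifyCohort(rs)$mGrade, classifyCohort(ss)$mGrade)
})

test_that("re-calibrated thresholds are honoured", {
  thr <- GradingThresholds(mg1Min = c(rs_epi = 1100, ss_epi = 1000),
                           mg2Max = c(rs_epi = 1200, ss_epi = 1100),
                           mg3Max = c(rs_epi = 1100, ss_epi = 1000))
  les <- baseLesion(adc_um2_s = 1050, high_b_hyperintense = 1,
                    t2_conspicuity = "clear")
  expect_identical(classifyLesion(les), 2L)           # published cut-offs
  expect_identical(classifyLesion(les, thresholds = thr), 3L)
})
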