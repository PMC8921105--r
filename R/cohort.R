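#' Lognormal parameters from a median and interquartile range
#'
#' Moment-matches a lognormal distribution to a "median (IQR)" summary:
#' \code{mu = log(median)} so the distribution's median is exact, and
#' \code{sigma} is the average of the two one-sided quartile estimates,
#' \deqn{\sigma = \frac{\log(q_3/median) + \log(median/q_1)}{2\, z_{0.75}}}
#' with \eqn{z_{0.75} = \Phi^{-1}(0.75) \approx 0.674490}. Averaging the two
#' sides makes the fit robust to the mild asymmetry of printed IQRs.
#'
#' @param median,q1,q3 summary statistics with \code{0 < q1 < median < q3}.
#' @return Named list with \code{mu} and \code{sigma} (both on the log
#'   scale), directly usable with [stats::rlnorm()].
#' @examples
#' lognormalFromMedianIQR(7.0, 5.3, 9.5)   # mu = log(7) = 1.9459
#' @export
lognormalFromMedianIQR <- function(median, q1, q3) {
  stopIfNot(all(q1 > 0) && all(q1 < median) && all(median < q3),
            "need 0 < q1 < median < q3")
  z75 <- stats::qnorm(0.75)
  list(mu = log(median),
       sigma = (log(q3 / median) + log(median / q1)) / (2 * z75))
}

.rlnormTriple <- function(n, params, prefix) {
  lp <- lognormalFromMedianIQR(params[[paste0(prefix, "Median")]],
                               params[[paste0(prefix, "Q1")]],
                               params[[paste0(prefix, "Q3")]])
  stats::rlnorm(n, lp$mu, lp$sigma)
}

## Truncated normal by inverse-CDF: exact, vectorized, one uniform per draw.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

.COHORT_COLS <- c("patient_id", "isup", "age", "psa", "prostate_volume_ml",
                  "psad", "infiltration_pct", "visible", "dwi_technique",
                  "adc_um2_s", "high_b_hyperintense", "t2_conspicuity",
                  "diameter_mm", "zone", "cross_zonal", "epe", "pirads")

## One ISUP group arm of n patients under its calibration row `pr`.
.generateGroup <- function(n, isupLevel, pr, rsEpiProb, ageBounds) {
  age <- .rtruncnorm(n, pr$ageMean, pr$ageSd, ageBounds[1], ageBounds[2])
  psa <- .rlnormTriple(n, pr, "psa")
  psad <- .rlnormTriple(n, pr, "psad")
  infiltration <- pmin(100, pmax(1, .rlnormTriple(n, pr, "inf")))
  visible <- stats::rbinom(n, 1, pr$visibilityProb)
  technique <- ifelse(stats::rbinom(n, 1, rsEpiProb) == 1, "rs_epi", "ss_epi")
  adcRs <- .rlnormTriple(n, pr, "adcRs")
  adcSs <- .rlnormTriple(n, pr, "adcSs")
  adc <- ifelse(technique == "rs_epi", adcRs, adcSs)
  highB <- stats::rbinom(n, 1, pr$highBProb)
  t2 <- sample(.T2_LEVELS, n, replace = TRUE,
               prob = c(pr$t2Discreet, pr$t2Overlayed, pr$t2Clear))
  diameter <- .rlnormTriple(n, pr, "diam")
  zone <- sample(.ZONE_LEVELS, n, replace = TRUE,
                 prob = c(pr$zonePZ, pr$zoneTZ, pr$zoneAS))
  crossZonal <- stats::rbinom(n, 1, pr$crossZonalProb)
  epe <- stats::rbinom(n, 1, pr$ct3Prob)
  pirads <- sample(.PIRADS_LEVELS, n, replace = TRUE,
                   prob = c(pr$pirads3, pr$pirads4, pr$pirads5))
  out <- data.frame(
    patient_id = rep(NA_character_, n), isup = rep(isupLevel, n),
    age = age, psa = psa,
    prostate_volume_ml = psa / psad, psad = psad,
    infiltration_pct = infiltration, visible = visible,
    dwi_technique = technique, adc_um2_s = adc,
    high_b_hyperintense = highB, t2_conspicuity = t2,
    diameter_mm = diameter, zone = zone, cross_zonal = crossZonal,
    epe = epe, pirads = pirads, stringsAsFactors = FALSE)
  ## invisible cancers carry no lesion descriptors
  inv <- out$visible == 0
  out[inv, c("dwi_technique", "t2_conspicuity", "zone")] <- NA_character_
  out[inv, c("adc_um2_s", "diameter_mm")] <- NA_real_
  out[inv, c("high_b_hyperintense", "cross_zonal", "epe", "pirads")] <-
    NA_integer_
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws \code{4 * n} synthetic patient records, \code{n} per biopsy ISUP
#' grade group (1, 2, 3, 4 = combined 4-5), from the per-group calibration
#' of a [CohortConfig]. Age is truncated normal; PSA, PSA density, biopsy
#' infiltration (clipped to 1-100%), lesion diameter and ADC are lognormal
#' via [lognormalFromMedianIQR()]; prostate volume is derived as
#' \code{psa / psad} so that PSA density is exactly consistent; the lesion
#' is MRI-visible with the group's visibility probability; the DWI technique
#' is rs-EPI with probability \code{rsEpiProb} and the lesion's ADC is drawn
#' from the technique-matching distribution of its group; binary and
#' categorical features come from the group's prevalences. Features are
#' sampled conditionally independent given the ISUP group (beyond the
#' technique-ADC link).
#'
#' Reproducibility: identical \code{(config, n, seed)} give an identical
#' cohort. Each group draws from its own substream derived from
#' \code{seed}, and the caller's RNG state is left untouched.
#'
#' @param config a [CohortConfig]; defaults to the packaged calibration.
#' @param n number of patients per ISUP group.
#' @param seed integer random seed.
#' @return data.frame with \code{4 * n} rows and columns
#'   \code{patient_id, isup, age, psa, prostate_volume_ml, psad,
#'   infiltration_pct, visible, dwi_technique, adc_um2_s,
#'   high_b_hyperintense, t2_conspicuity, diameter_mm, zone, cross_zonal,
#'   epe, pirads}. Lesion columns are \code{NA} when \code{visible = 0}.
#' @examples
#' cohort <- generateCohort(n = 50, seed = 7)
#' table(cohort$isup, cohort$visible)
#' @export
generateCohort <- function(config = defaultCohortConfig(), n = 50,
                           seed = 1) {
  stopIfNot(is(config, "CohortConfig"), "config must be a CohortConfig")
  validObject(config)
  stopIfNot(length(n) == 1L && n >= 0 && n == round(n),
            "n must be a single non-negative integer")
  if (n == 0L) {
    out <- .generateGroup(0L, 1L, cohortParams(config)[1, ],
                          config@rsEpiProb, config@ageBounds)
    return(out[, .COHORT_COLS])
  }
  groupSeeds <- withSeed(seed,
                         sample.int(.Machine$integer.max - 1L, 4L))
  p <- cohortParams(config)
  parts <- lapply(.ISUP_LEVELS, function(g)
    withSeed(groupSeeds[g],
             .generateGroup(n, g, p[g, ], config@rsEpiProb,
                            config@ageBounds)))
  out <- do.call(rbind, parts)
  out$patient_id <- sprintf("P%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, .COHORT_COLS]
}

#' Write or read a cohort CSV
#'
#' The cohort CSV schema is the column set documented in
#' [generateCohort()]; missing lesion fields of invisible cancers are
#' written as empty strings. ADC is in \eqn{\mu m^2/s}, diameter in mm, PSA
#' in ng/ml, prostate volume in ml, PSA density in ng/ml/cm3.
#' `readCohortCsv()` validates the schema and the record invariants
#' (positive PSA and volume, PSA density consistent with PSA/volume to a
#' relative 1e-9, age within 40-95, unique patient ids, ISUP in 1-5 with 5
#' merged into the combined 4-5 group) and reports the offending rows.
#'
#' @param cohort a cohort data.frame.
#' @param path CSV file path.
#' @return `writeCohortCsv()` returns `path` invisibly; `readCohortCsv()`
#'   the validated cohort data.frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeCohortCsv(generateCohort(n = 5, seed = 3), f)
#' nrow(readCohortCsv(f))
#' @export
writeCohortCsv <- function(cohort, path) {
  stopIfNot(is.data.frame(cohort) &&
              identical(colnames(cohort), .COHORT_COLS),
            "cohort does not follow the documented CSV schema")
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  validateCohort(d)
}

#' Validate a cohort table
#'
#' Schema and invariant checks shared by [readCohortCsv()] and
#' [runAnalysis()]; errors name the violated rule and the first offending
#' rows.
#'
#' @param cohort a cohort data.frame (schema of [generateCohort()]).
#' @return The cohort, invisibly modified only in that character blanks are
#'   \code{NA} and ISUP 5 is merged into level 4.
#' @export
validateCohort <- function(cohort) {
  stopIfNot(is.data.frame(cohort), "cohort must be a data.frame")
  miss <- setdiff(.COHORT_COLS, colnames(cohort))
  stopIfNot(length(miss) == 0L, "cohort is missing column(s): %s",
            paste(miss, collapse = ", "))
  cohort <- cohort[, .COHORT_COLS]
  for (col in c("dwi_technique", "t2_conspicuity", "zone"))
    cohort[[col]][!is.na(cohort[[col]]) & cohort[[col]] == ""] <- NA
  .offenders <- function(bad, what) {
    stopIfNot(!any(bad), "%s (rows %s)", what,
              paste(utils::head(which(bad), 5), collapse = ", "))
  }
  .offenders(duplicated(cohort$patient_id), "duplicate patient_id")
  .offenders(!cohort$isup %in% 1:5, "isup must lie in 1..5")
  if (any(cohort$isup == 5)) {
    message("merging ", sum(cohort$isup == 5),
            " ISUP 5 record(s) into the combined 4-5 group")
    cohort$isup[cohort$isup == 5] <- 4
  }
  .offenders(!is.finite(cohort$psa) | cohort$psa <= 0,
             "psa must be positive")
  .offenders(!is.finite(cohort$prostate_volume_ml) |
               cohort$prostate_volume_ml <= 0,
             "prostate_volume_ml must be positive")
  .offenders(abs(cohort$psad - cohort$psa / cohort$prostate_volume_ml) >
               1e-9 * pmax(cohort$psad, 1e-12),
             "psad must equal psa / prostate_volume_ml")
  .offenders(cohort$age < 40 | cohort$age > 95, "age must lie in [40, 95]")
  .offenders(!cohort$visible %in% c(0, 1), "visible must be 0 or 1")
  vis <- cohort$visible == 1
  .offenders(vis & (is.na(cohort$adc_um2_s) | cohort$adc_um2_s <= 0 |
                      cohort$adc_um2_s >= 4000),
             "visible lesions need adc_um2_s in (0, 4000)")
  .offenders(vis & (is.na(cohort$diameter_mm) | cohort$diameter_mm <= 0),
             "visible lesions need a positive diameter_mm")
  .offenders(vis & !cohort$dwi_technique %in% .TECHNIQUES,
             "visible lesions need dwi_technique rs_epi or ss_epi")
  .offenders(vis & !cohort$t2_conspicuity %in% .T2_LEVELS,
             "visible lesions need a valid t2_conspicuity")
  .offenders(vis & !cohort$zone %in% .ZONE_LEVELS,
             "visible lesions need zone PZ, TZ or AS")
  for (col in c("high_b_hyperintense", "cross_zonal", "epe"))
    .offenders(vis & !cohort[[col]] %in% c(0, 1),
               sprintf("visible lesions need binary %s", col))
  .offenders(vis & !cohort$pirads %in% .PIRADS_LEVELS,
             "visible lesions need pirads in 3..5")
  cohort
}
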