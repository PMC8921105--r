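#' @import methods
NULL

## Ordinal level sets shared across the package. ISUP grade group 4 stands
## for the combined 4-5 group; raw 5 input is mapped onto it on read.
.ISUP_LEVELS <- 1:4
.MG_LEVELS <- 1:3
.T2_LEVELS <- c("discreet", "overlayed", "clear")
.ZONE_LEVELS <- c("PZ", "TZ", "AS")
.TECHNIQUES <- c("rs_epi", "ss_epi")
.PIRADS_LEVELS <- 3:5

#' ADC decision thresholds of the MRI grading rule
#'
#' Per-technique apparent diffusion coefficient (ADC) cut-offs, in
#' \eqn{\mu m^2/s}, used by the grading rule: \code{mg1Min} is the strict
#' lower bound a lesion must exceed for mG1, \code{mg2Max} the strict upper
#' bound for mG2, and \code{mg3Max} the strict upper bound for mG3. Each slot
#' is a named numeric vector with entries \code{rs_epi} and \code{ss_epi};
#' readout-segmented DWI runs 100 \eqn{\mu m^2/s} above single-shot DWI.
#'
#' @slot mg1Min named numeric, strict lower ADC bound for grade mG1.
#' @slot mg2Max named numeric, strict upper ADC bound for grade mG2.
#' @slot mg3Max named numeric, strict upper ADC bound for grade mG3.
#' @seealso [GradingThresholds()] for the constructor with the published
#'   defaults, [classifyLesion()] for the rule that consumes them.
#' @exportClass GradingThresholds
setClass("GradingThresholds",
  representation(mg1Min = "numeric", mg2Max = "numeric", mg3Max = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("mg1Min", "mg2Max", "mg3Max")) {
      v <- slot(object, s)
      if (!identical(sort(names(v)), sort(.TECHNIQUES)))
        msg <- c(msg, sprintf("slot '%s' must be named %s",
                              s, paste(.TECHNIQUES, collapse = ", ")))
      if (any(!is.finite(v)) || any(v <= 0))
        msg <- c(msg, sprintf("slot '%s' must be finite and positive", s))
    }
    if (!length(msg)) {
      for (tech in .TECHNIQUES) {
        if (!(object@mg3Max[tech] <= object@mg1Min[tech] &&
              object@mg1Min[tech] < object@mg2Max[tech]))
          msg <- c(msg, sprintf(
            "need mg3Max <= mg1Min < mg2Max for technique '%s'", tech))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' ISUP-by-MRI-grade cross-tabulation
#'
#' A 4 x 3 non-negative integer count matrix with biopsy ISUP grade groups
#' (1, 2, 3, 4 = combined 4-5) on the rows and MRI grading groups (mG1-mG3)
#' on the columns. The published study cross-tabulation is available through
#' [table3CrossTab()].
#'
#' @slot counts integer matrix of cell counts, rows ISUP ascending, columns
#'   mG ascending, with dimnames.
#' @seealso [crossTab()], [crossTabFromLabels()], [riskTable()],
#'   [kendallTauBFromTable()].
#' @exportClass CrossTab
setClass("CrossTab", representation(counts = "matrix"),
  validity = function(object) {
    m <- object@counts
    msg <- character()
    if (!is.numeric(m) || nrow(m) != 4L || ncol(m) != 3L)
      msg <- c(msg, "counts must be a numeric 4 x 3 matrix")
    else {
      if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be non-negative integers")
      if (is.null(dimnames(m)) ||
          !identical(rownames(m), paste0("ISUP", .ISUP_LEVELS)) ||
          !identical(colnames(m), paste0("mG", .MG_LEVELS)))
        msg <- c(msg, "counts must carry ISUP1..ISUP4 / mG1..mG3 dimnames")
    }
    if (length(msg)) msg else TRUE
  })

#' Per-grade risk of clinically significant and high-grade cancer
#'
#' For each MRI grading group, the column-conditional proportion of lesions
#' with biopsy ISUP grade group >= 2 (clinically significant cancer) and
#' >= 3 (high grade), with Wilson score confidence intervals.
#'
#' @slot n integer column totals per grade.
#' @slot riskGe2,riskGe3 numeric proportions per grade, in [0, 1].
#' @slot ciGe2,ciGe3 3 x 2 matrices of Wilson interval bounds (low, high).
#' @slot conf confidence level of the intervals.
#' @seealso [riskTable()], [wilsonInterval()].
#' @exportClass RiskTable
setClass("RiskTable",
  representation(n = "integer", riskGe2 = "numeric", riskGe3 = "numeric",
                 ciGe2 = "matrix", ciGe3 = "matrix", conf = "numeric"),
  validity = function(object) {
    msg <- character()
    grades <- paste0("mG", .MG_LEVELS)
    if (length(object@n) != 3L || any(object@n < 1L))
      msg <- c(msg, "n must hold three positive column totals")
    for (s in c("riskGe2", "riskGe3")) {
      v <- slot(object, s)
      if (length(v) != 3L || any(v < 0) || any(v > 1))
        msg <- c(msg, sprintf("%s must be three proportions in [0, 1]", s))
    }
    for (s in c("ciGe2", "ciGe3")) {
      ci <- slot(object, s)
      if (!is.matrix(ci) || !identical(dim(ci), c(3L, 2L)))
        msg <- c(msg, sprintf("%s must be a 3 x 2 matrix", s))
    }
    if (!length(msg)) {
      if (any(object@riskGe3 > object@riskGe2 + 1e-12))
        msg <- c(msg, "riskGe3 must not exceed riskGe2 in any grade")
      if (any(object@ciGe2[, 1] > object@riskGe2 + 1e-12) ||
          any(object@ciGe2[, 2] < object@riskGe2 - 1e-12) ||
          any(object@ciGe3[, 1] > object@riskGe3 + 1e-12) ||
          any(object@ciGe3[, 2] < object@riskGe3 - 1e-12))
        msg <- c(msg, "confidence intervals must contain their point estimate")
      if (length(object@conf) != 1L || object@conf <= 0 || object@conf >= 1)
        msg <- c(msg, "conf must be a single value in (0, 1)")
      if (!identical(names(object@n), grades))
        msg <- c(msg, "slots must be named mG1..mG3")
    }
    if (length(msg)) msg else TRUE
  })

## Columns of the per-group parameter table of a CohortConfig, in order.
## Quartile triples are (median, q1, q3) blocks; probabilities in [0, 1].
.CONFIG_COLS <- c(
  "ageMean", "ageSd",
  "psaMedian", "psaQ1", "psaQ3",
  "psadMedian", "psadQ1", "psadQ3",
  "infMedian", "infQ1", "infQ3",
  "visibilityProb",
  "zonePZ", "zoneTZ", "zoneAS",
  "diamMedian", "diamQ1", "diamQ3",
  "crossZonalProb", "ct3Prob", "highBProb",
  "adcRsMedian", "adcRsQ1", "adcRsQ3",
  "adcSsMedian", "adcSsQ1", "adcSsQ3",
  "t2Discreet", "t2Overlayed", "t2Clear",
  "pirads3", "pirads4", "pirads5")

.CONFIG_TRIPLES <- list(
  psa = c("psaQ1", "psaMedian", "psaQ3"),
  psad = c("psadQ1", "psadMedian", "psadQ3"),
  infiltration = c("infQ1", "infMedian", "infQ3"),
  diameter = c("diamQ1", "diamMedian", "diamQ3"),
  adcRs = c("adcRsQ1", "adcRsMedian", "adcRsQ3"),
  adcSs = c("adcSsQ1", "adcSsMedian", "adcSsQ3"))

.CONFIG_SIMPLEXES <- list(
  zone = c("zonePZ", "zoneTZ", "zoneAS"),
  t2 = c("t2Discreet", "t2Overlayed", "t2Clear"),
  pirads = c("pirads3", "pirads4", "pirads5"))

.CONFIG_PROBS <- c("visibilityProb", "crossZonalProb", "ct3Prob", "highBProb",
                   unlist(.CONFIG_SIMPLEXES, use.names = FALSE))

#' Calibration of the synthetic cohort generator
#'
#' Holds one row of distribution parameters per ISUP grade group (age
#' mean/SD; median and quartiles of PSA, PSA density, biopsy infiltration,
#' lesion diameter and per-technique ADC; prevalence of lesion visibility,
#' cross-zonal growth, extraprostatic extension (cT3) and high-b-value
#' hyperintensity; zone, T2-conspicuity and PI-RADS category probabilities),
#' plus cohort-wide settings: the probability of a readout-segmented DWI
#' acquisition and the truncation bounds of the age distribution.
#'
#' @slot params data.frame with rows \code{ISUP1..ISUP4} and one column per
#'   parameter (see [defaultCohortConfig()]).
#' @slot rsEpiProb probability that a patient's DWI is rs-EPI (else ss-EPI).
#' @slot ageBounds numeric length-2 truncation bounds for age, in years.
#' @seealso [defaultCohortConfig()], [table2Calibration()],
#'   [generateCohort()].
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(params = "data.frame", rsEpiProb = "numeric",
                 ageBounds = "numeric"),
  validity = function(object) {
    p <- object@params
    msg <- character()
    if (!identical(rownames(p), paste0("ISUP", .ISUP_LEVELS)))
      msg <- c(msg, "params must have rows ISUP1..ISUP4")
    miss <- setdiff(.CONFIG_COLS, colnames(p))
    if (length(miss))
      return(paste("params is missing columns:", paste(miss, collapse = ", ")))
    if (any(!vapply(p[.CONFIG_COLS], is.numeric, logical(1))))
      return("all params columns must be numeric")
    if (any(!is.finite(as.matrix(p[.CONFIG_COLS]))))
      msg <- c(msg, "params must be finite")
    for (nm in names(.CONFIG_TRIPLES)) {
      tri <- .CONFIG_TRIPLES[[nm]]
      ok <- p[[tri[1]]] > 0 & p[[tri[1]]] < p[[tri[2]]] & p[[tri[2]]] < p[[tri[3]]]
      if (any(!ok))
        msg <- c(msg, sprintf("need 0 < q1 < median < q3 for '%s'", nm))
    }
    pr <- as.matrix(p[.CONFIG_PROBS])
    if (any(pr < 0 | pr > 1))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    for (nm in names(.CONFIG_SIMPLEXES)) {
      s <- rowSums(p[.CONFIG_SIMPLEXES[[nm]]])
      if (any(abs(s - 1) > 1e-9))
        msg <- c(msg, sprintf("'%s' probabilities must sum to 1 per group", nm))
    }
    if (any(p$ageSd <= 0)) msg <- c(msg, "ageSd must be positive")
    if (length(object@rsEpiProb) != 1L || object@rsEpiProb < 0 ||
        object@rsEpiProb > 1)
      msg <- c(msg, "rsEpiProb must be a single probability")
    if (length(object@ageBounds) != 2L ||
        object@ageBounds[1] >= object@ageBounds[2])
      msg <- c(msg, "ageBounds must be an increasing pair")
    if (length(msg)) msg else TRUE
  })

#' Result of an association statistic
#'
#' A single correlation or ANOVA result: the statistic's name
#' (\code{kendall_tau_b}, \code{spearman_rho} or \code{anova_F}), its value,
#' the sample size, and (optionally) raw and multiplicity-adjusted p values.
#'
#' @slot statisticName character, one of the three statistic identifiers.
#' @slot value the statistic (tau/rho in [-1, 1]; F >= 0).
#' @slot n integer sample size.
#' @slot pValue,pAdjusted p values in [0, 1]; \code{NA} when not computed.
#' @seealso [kendallTauB()], [spearmanRho()], [oneWayAnova()].
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(statisticName = "character", value = "numeric",
                 n = "integer", pValue = "numeric", pAdjusted = "numeric"),
  prototype(pValue = NA_real_, pAdjusted = NA_real_),
  validity = function(object) {
    msg <- character()
    if (!object@statisticName %in% c("kendall_tau_b", "spearman_rho", "anova_F"))
      msg <- c(msg, "unknown statisticName")
    v <- object@value
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, "value must be a single finite number")
    else if (object@statisticName %in% c("kendall_tau_b", "spearman_rho") &&
             (v < -1 - 1e-12 || v > 1 + 1e-12))
      msg <- c(msg, "correlation value must lie in [-1, 1]")
    else if (object@statisticName == "anova_F" && v < 0)
      msg <- c(msg, "F statistic must be non-negative")
    for (s in c("pValue", "pAdjusted")) {
      pv <- slot(object, s)
      if (!is.na(pv) && (pv < 0 || pv > 1))
        msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
    }
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (length(msg)) msg else TRUE
  })

#' Multivariable linear model result
#'
#' Least-squares coefficients with normal-theory 95% confidence intervals
#' for the prediction of the (numeric) ISUP grade group level from lesion
#' features, together with the reference level used for each categorical
#' term.
#'
#' @slot coefficients named numeric vector of estimates.
#' @slot ci95 matrix with one row per coefficient and columns
#'   \code{low}, \code{high}.
#' @slot referenceLevels named character vector, reference level per
#'   categorical term (empty when none).
#' @slot n integer number of observations used in the fit.
#' @slot sigma residual standard deviation.
#' @seealso [linearModelFit()].
#' @exportClass LinearModelResult
setClass("LinearModelResult",
  representation(coefficients = "numeric", ci95 = "matrix",
                 referenceLevels = "character", n = "integer",
                 sigma = "numeric"),
  validity = function(object) {
    msg <- character()
    b <- object@coefficients
    ci <- object@ci95
    if (is.null(names(b))) msg <- c(msg, "coefficients must be named")
    if (!is.matrix(ci) || nrow(ci) != length(b) || ncol(ci) != 2L)
      msg <- c(msg, "ci95 must be a (#coefficients) x 2 matrix")
    else if (any(ci[, 1] > b + 1e-12) || any(ci[, 2] < b - 1e-12))
      msg <- c(msg, "each confidence interval must contain its estimate")
    if (length(msg)) msg else TRUE
  })

#' End-to-end analysis report
#'
#' Everything [runAnalysis()] derives from a cohort: the per-ISUP cohort
#' summary, the grade-by-ISUP [CrossTab], the [RiskTable], the table of
#' association statistics of every parameter with the ISUP grade group, the
#' multivariable [LinearModelResult] (rs-EPI lesions; \code{NULL} when the
#' cohort cannot support the fit), and a provenance block recording the
#' package version, configuration hash and grading thresholds.
#'
#' @slot cohortSummary data.frame, one row per ISUP group.
#' @slot crossTab a [CrossTab].
#' @slot riskTable a [RiskTable].
#' @slot associations data.frame of association statistics.
#' @slot model a [LinearModelResult] or \code{NULL}.
#' @slot provenance named list (package version, config hash, thresholds,
#'   timestamp).
#' @exportClass AnalysisReport
setClass("AnalysisReport",
  representation(cohortSummary = "data.frame", crossTab = "CrossTab",
                 riskTable = "RiskTable", associations = "data.frame",
                 model = "ANY", provenance = "list"))
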