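#' @describeIn GradingThresholds-class Compact threshold display.
#' @param object the object to display.
setMethod("show", "GradingThresholds", function(object) {
  cat("MRI grading ADC thresholds (um^2/s)\n")
  m <- rbind(`mG1 (ADC >)` = object@mg1Min,
             `mG2 (ADC <)` = object@mg2Max,
             `mG3 (ADC <)` = object@mg3Max)
  print(m)
  invisible(NULL)
})

#' @describeIn CrossTab-class Prints the count matrix with its marginals.
#' @param object the object to display.
setMethod("show", "CrossTab", function(object) {
  m <- counts(object)
  cat("ISUP x MRI-grade cross-tabulation (", sum(m), " graded lesions)\n",
      sep = "")
  print(cbind(m, All = rowSums(m)))
  cat("All:", paste(colSums(m), collapse = " / "), "\n")
  invisible(NULL)
})

#' @describeIn RiskTable-class Per-grade risks with their intervals.
#' @param object the object to display.
setMethod("show", "RiskTable", function(object) {
  cat(sprintf("Risk of ISUP >= 2 / >= 3 per MRI grading group (Wilson %g%% CI)\n",
              100 * object@conf))
  d <- data.frame(
    n = object@n,
    risk_ge2 = sprintf("%2.0f%% (%2.0f-%2.0f%%)",
                       roundHalfUp(100 * object@riskGe2),
                       100 * object@ciGe2[, 1], 100 * object@ciGe2[, 2]),
    risk_ge3 = sprintf("%2.0f%% (%2.0f-%2.0f%%)",
                       roundHalfUp(100 * object@riskGe3),
                       100 * object@ciGe3[, 1], 100 * object@ciGe3[, 2]),
    row.names = names(object@n))
  print(d)
  invisible(NULL)
})

#' @describeIn CohortConfig-class Summary of the calibration.
#' @param object the object to display.
setMethod("show", "CohortConfig", function(object) {
  p <- cohortParams(object)
  cat("Synthetic cohort calibration (4 ISUP grade groups)\n")
  cat(sprintf("  rs-EPI probability %.2f; age bounds [%g, %g]\n",
              object@rsEpiProb, object@ageBounds[1], object@ageBounds[2]))
  print(p[, c("ageMean", "psaMedian", "visibilityProb", "crossZonalProb",
              "ct3Prob", "highBProb", "adcRsMedian", "adcSsMedian")])
  cat("  (", ncol(p), " parameters per group; see cohortParams())\n",
      sep = "")
  invisible(NULL)
})

#' @describeIn AssociationResult-class One-line statistic display.
#' @param object the object to display.
setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("%s = %.4f (n = %d%s)\n", object@statisticName, object@value,
              object@n,
              if (is.na(object@pValue)) ""
              else sprintf(", p = %.3g", object@pValue)))
  invisible(NULL)
})

#' @describeIn LinearModelResult-class Coefficient table.
#' @param object the object to display.
setMethod("show", "LinearModelResult", function(object) {
  cat(sprintf("Linear model of ISUP grade group level (n = %d, sigma = %.3f)\n",
              object@n, object@sigma))
  print(data.frame(B = object@coefficients,
                   low = object@ci95[, 1], high = object@ci95[, 2]))
  if (length(object@referenceLevels))
    cat("Reference levels:",
        paste(names(object@referenceLevels), object@referenceLevels,
              sep = " = ", collapse = ", "), "\n")
  invisible(NULL)
})

#' @describeIn AnalysisReport-class Report overview.
#' @param object the object to display.
setMethod("show", "AnalysisReport", function(object) {
  cat("mpMRIgrade analysis report (schema ",
      object@provenance$schema_version, ")\n", sep = "")
  show(object@crossTab)
  show(object@riskTable)
  cat("Associations with the ISUP grade group:\n")
  print(object@associations[, c("parameter", "n", "tau_b", "spearman_rho",
                                "anova_p_bonferroni")], digits = 3)
  if (!is.null(object@model)) show(object@model)
  invisible(NULL)
})
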