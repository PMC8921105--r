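#' Grading thresholds with the published defaults
#'
#' ADC cut-offs of the MRI grading rule in \eqn{\mu m^2/s}: a lesion is
#' eligible for mG1 when its ADC lies strictly above \code{mg1Min}, for mG2
#' strictly below \code{mg2Max} and for mG3 strictly below \code{mg3Max},
#' always for the matching DWI technique. Defaults are the published values
#' (rs-EPI: > 900 / < 1000 / < 900; ss-EPI: > 800 / < 900 / < 800). Other
#' institutions can re-calibrate by passing their own cut-offs; validity
#' enforces \code{mg3Max <= mg1Min < mg2Max} per technique.
#'
#' @param mg1Min,mg2Max,mg3Max named numeric vectors with entries
#'   \code{rs_epi} and \code{ss_epi}.
#' @return A validated [GradingThresholds].
#' @examples
#' GradingThresholds()
#' GradingThresholds(mg1Min = c(rs_epi = 850, ss_epi = 750),
#'                   mg2Max = c(rs_epi = 950, ss_epi = 850),
#'                   mg3Max = c(rs_epi = 850, ss_epi = 750))
#' @export
GradingThresholds <- function(mg1Min = c(rs_epi = 900, ss_epi = 800),
                              mg2Max = c(rs_epi = 1000, ss_epi = 900),
                              mg3Max = c(rs_epi = 900, ss_epi = 800)) {
  new("GradingThresholds", mg1Min = mg1Min[.TECHNIQUES],
      mg2Max = mg2Max[.TECHNIQUES], mg3Max = mg3Max[.TECHNIQUES])
}

.thresholdFor <- function(thresholds, grade, technique) {
  stopIfNot(all(technique %in% .TECHNIQUES),
            "unknown DWI technique: %s",
            paste(setdiff(unique(technique), .TECHNIQUES), collapse = ", "))
  slotName <- c("mg1Min", "mg2Max", "mg3Max")[grade]
  slot(thresholds, slotName)[technique]
}

#' ADC criterion of a single grading row
#'
#' Tests whether an ADC value satisfies the diffusion criterion of the given
#' MRI grading group: mG1 requires ADC strictly above its technique-specific
#' minimum; mG2 and mG3 require ADC strictly below their maxima. Values
#' exactly at a threshold fail the strict comparison and fall through to the
#' next rule of [classifyLesion()].
#'
#' @param grade integer MRI grading group (1, 2 or 3).
#' @param technique \code{"rs_epi"} or \code{"ss_epi"} (vectorized).
#' @param adc ADC value(s) in \eqn{\mu m^2/s}; must be positive.
#' @param thresholds a [GradingThresholds].
#' @return Logical vector: criterion satisfied.
#' @examples
#' adcMeets(1, "rs_epi", 901)   # TRUE, above the mG1 minimum
#' adcMeets(3, "ss_epi", 800)   # FALSE, boundary fails the strict <
#' @export
adcMeets <- function(grade, technique, adc,
                     thresholds = GradingThresholds()) {
  stopIfNot(length(grade) == 1L && grade %in% .MG_LEVELS,
            "grade must be one of 1, 2, 3")
  stopIfNot(all(is.finite(adc)) && all(adc > 0), "adc must be positive")
  thr <- .thresholdFor(thresholds, grade, technique)
  unname(if (grade == 1L) adc > thr else adc < thr)
}

## Vectorized grading core. All arguments recycled to common length n;
## returns an integer vector of grades in {1, 2, 3}.
##
## Precedence: mG3 first (most aggressive satisfied rule wins), then mG1,
## mG2 is the residual class. EPE alone forces mG3; under the default
## connector reading the remaining mG3 route requires low ADC AND high-b
## hyperintensity AND clear T2 jointly, while `mg3T2Alone = TRUE` switches
## to the alternative reading in which a clearly conspicuous T2 lesion (or
## low ADC with high-b signal) suffices.
.classifyVec <- function(technique, adc, highB, t2, crossZonal, epe,
                         thresholds, mg3T2Alone = FALSE) {
  stopIfNot(all(t2 %in% .T2_LEVELS), "t2 conspicuity must be one of %s",
            paste(.T2_LEVELS, collapse = ", "))
  stopIfNot(all(highB %in% c(0, 1)) && all(crossZonal %in% c(0, 1)) &&
            all(epe %in% c(0, 1)), "binary features must be 0 or 1")
  adc3 <- adcMeets(3L, technique, adc, thresholds)
  adc1 <- adcMeets(1L, technique, adc, thresholds)
  mg3 <- if (mg3T2Alone) {
    epe == 1 | (adc3 & highB == 1) | t2 == "clear"
  } else {
    epe == 1 | (adc3 & highB == 1 & t2 == "clear")
  }
  mg1 <- !mg3 & adc1 & t2 == "discreet" & crossZonal == 0 & epe == 0
  ifelse(mg3, 3L, ifelse(mg1, 1L, 2L))
}

.LESION_FIELDS <- c("dwi_technique", "adc_um2_s", "high_b_hyperintense",
                    "t2_conspicuity", "cross_zonal", "epe")

#' Assign an MRI grading group to a visible lesion
#'
#' Applies the deterministic grading rule to one lesion-feature record. The
#' rule is total: every feature combination receives exactly one grade.
#' Precedence is mG3, then mG1, with mG2 as the residual class:
#' \itemize{
#'   \item \strong{mG3} if the lesion shows extraprostatic extension
#'     (\code{epe = 1}), or if its ADC lies strictly below the mG3 maximum
#'     \emph{and} it is hyperintense on high-b-value images \emph{and} its
#'     T2 conspicuity is \code{"clear"}.
#'   \item otherwise \strong{mG1} if the ADC lies strictly above the mG1
#'     minimum, T2 conspicuity is \code{"discreet"}, and there is neither
#'     cross-zonal growth nor extraprostatic extension.
#'   \item otherwise \strong{mG2}.
#' }
#'
#' @param features named list or one-row data.frame with fields
#'   \code{dwi_technique} (\code{"rs_epi"}/\code{"ss_epi"}),
#'   \code{adc_um2_s}, \code{high_b_hyperintense} (0/1),
#'   \code{t2_conspicuity} (\code{"discreet"}, \code{"overlayed"},
#'   \code{"clear"}), \code{cross_zonal} (0/1), \code{epe} (0/1).
#' @param thresholds a [GradingThresholds].
#' @param mg3T2Alone logical; alternative connector reading under which a
#'   \code{"clear"} T2 lesion alone (or low ADC with high-b signal alone)
#'   already qualifies as mG3. Default \code{FALSE}.
#' @return Integer MRI grading group in \code{1:3}.
#' @examples
#' classifyLesion(list(dwi_technique = "rs_epi", adc_um2_s = 1100,
#'                     high_b_hyperintense = 0, t2_conspicuity = "discreet",
#'                     cross_zonal = 0, epe = 0))            # 1
#' classifyLesion(list(dwi_technique = "rs_epi", adc_um2_s = 704,
#'                     high_b_hyperintense = 1, t2_conspicuity = "clear",
#'                     cross_zonal = 1, epe = 0))            # 3
#' @export
classifyLesion <- function(features, thresholds = GradingThresholds(),
                           mg3T2Alone = FALSE) {
  features <- as.list(features)
  missing <- .LESION_FIELDS[vapply(.LESION_FIELDS, function(f) {
    is.null(features[[f]]) || length(features[[f]]) != 1L ||
      is.na(features[[f]])
  }, logical(1))]
  stopIfNot(length(missing) == 0L, "missing lesion field(s): %s",
            paste(missing, collapse = ", "))
  .classifyVec(features$dwi_technique, features$adc_um2_s,
               features$high_b_hyperintense, features$t2_conspicuity,
               features$cross_zonal, features$epe, thresholds, mg3T2Alone)
}

#' Grade every patient of a cohort
#'
#' Applies [classifyLesion()] to every MRI-visible lesion of a cohort table
#' (see [generateCohort()] for the schema). Patients whose cancer was not
#' visible on mpMRI are labelled \code{"not_visible"} and are excluded from
#' any downstream cross-tabulation. Output order equals input order.
#'
#' @param cohort data.frame with columns \code{patient_id}, \code{visible}
#'   and the lesion fields of [classifyLesion()] (empty/NA when
#'   \code{visible = 0}).
#' @inheritParams classifyLesion
#' @return data.frame with columns \code{patient_id} and \code{mGrade}
#'   (\code{"mG1"}, \code{"mG2"}, \code{"mG3"} or \code{"not_visible"}).
#' @examples
#' cohort <- generateCohort(n = 5, seed = 11)
#' classifyCohort(cohort)
#' @export
classifyCohort <- function(cohort, thresholds = GradingThresholds(),
                           mg3T2Alone = FALSE) {
  stopIfNot(is.data.frame(cohort), "cohort must be a data.frame")
  if (nrow(cohort) == 0L)
    return(data.frame(patient_id = character(), mGrade = character()))
  stopIfNot(!anyDuplicated(cohort$patient_id),
            "duplicate patient_id: %s",
            paste(unique(cohort$patient_id[duplicated(cohort$patient_id)]),
                  collapse = ", "))
  vis <- cohort$visible == 1
  grade <- rep("not_visible", nrow(cohort))
  if (any(vis)) {
    sub <- cohort[vis, , drop = FALSE]
    bad <- .LESION_FIELDS[vapply(.LESION_FIELDS, function(f)
      is.null(sub[[f]]) || anyNA(sub[[f]]), logical(1))]
    stopIfNot(length(bad) == 0L,
              "visible lesions have missing field(s): %s",
              paste(bad, collapse = ", "))
    g <- .classifyVec(sub$dwi_technique, sub$adc_um2_s,
                      sub$high_b_hyperintense, sub$t2_conspicuity,
                      sub$cross_zonal, sub$epe, thresholds, mg3T2Alone)
    grade[vis] <- paste0("mG", g)
  }
  data.frame(patient_id = cohort$patient_id, mGrade = grade,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate ISUP grade groups against MRI grades
#'
#' Counts (ISUP, mG) label pairs into a [CrossTab]. Raw ISUP 5 labels are
#' accepted and merged into level 4 (the combined 4-5 group) with a message.
#'
#' @param isup integer vector of biopsy ISUP grade groups (1-5; 5 is merged
#'   into 4).
#' @param mGrade integer vector in \code{1:3}, or character
#'   \code{"mG1"}-\code{"mG3"}, parallel to \code{isup}.
#' @return A [CrossTab]; its total equals \code{length(isup)}.
#' @examples
#' counts(crossTabFromLabels(c(1, 1, 4), c(1, 2, 3)))
#' @export
crossTabFromLabels <- function(isup, mGrade) {
  stopIfNot(length(isup) == length(mGrade),
            "isup and mGrade must have equal length")
  if (is.character(mGrade)) mGrade <- match(mGrade, paste0("mG", .MG_LEVELS))
  stopIfNot(all(isup %in% 1:5), "isup labels must lie in 1..5")
  stopIfNot(all(mGrade %in% .MG_LEVELS), "mGrade labels must lie in 1..3")
  if (any(isup == 5)) {
    message("merging ", sum(isup == 5), " ISUP 5 label(s) into the ",
            "combined 4-5 group")
    isup[isup == 5] <- 4
  }
  m <- table(factor(isup, levels = .ISUP_LEVELS),
             factor(mGrade, levels = .MG_LEVELS))
  crossTab(matrix(as.integer(m), nrow = 4))
}
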