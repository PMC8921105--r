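#' Multivariable linear prediction of the ISUP grade group
#'
#' Ordinary least-squares fit of the (numeric) biopsy ISUP grade group level
#' on lesion covariates, the fixed-effects analog of a mixed model: with a
#' single index lesion per patient there is no within-patient replication,
#' so no random effect is identifiable and the fixed-effects fit is the
#' whole model. Categorical columns (character or factor) are dummy-coded
#' against the reference level given in \code{referenceLevels} (first level
#' otherwise); in the packaged analysis the MRI grading group enters with
#' mG3 as reference. Confidence intervals are normal-theory (t) intervals.
#'
#' @param response numeric vector (the ISUP grade group level).
#' @param design data.frame of covariates, one row per observation; an
#'   empty / zero-column design fits the intercept-only model. Must be full
#'   rank.
#' @param referenceLevels named character vector mapping categorical column
#'   names to their reference level.
#' @return A [LinearModelResult].
#' @examples
#' cohort <- generateCohort(n = 100, seed = 5)
#' vis <- cohort[cohort$visible == 1 & cohort$dwi_technique == "rs_epi", ]
#' vis$mGrade <- classifyCohort(vis)$mGrade
#' fit <- linearModelFit(vis$isup,
#'                       vis[, c("cross_zonal", "epe", "adc_um2_s", "mGrade")],
#'                       referenceLevels = c(mGrade = "mG3"))
#' coef(fit)
#' @export
linearModelFit <- function(response, design = NULL,
                           referenceLevels = NULL) {
  stopIfNot(is.numeric(response) && length(response) >= 2L,
            "response must be a numeric vector")
  if (is.null(design) || ncol(as.data.frame(design)) == 0L)
    design <- data.frame(row.names = seq_along(response))
  design <- as.data.frame(design)
  stopIfNot(nrow(design) == length(response),
            "design must have one row per response value")
  refs <- character()
  for (col in colnames(design)) {
    v <- design[[col]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      ref <- if (col %in% names(referenceLevels))
        referenceLevels[[col]] else levels(v)[1]
      stopIfNot(ref %in% levels(v),
                "reference level '%s' not present in column '%s'", ref, col)
      design[[col]] <- stats::relevel(v, ref = ref)
      refs[col] <- ref
    }
  }
  dat <- cbind(.response = response, design)
  fit <- stats::lm(.response ~ ., data = dat)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  stopIfNot(length(aliased) == 0L,
            "design is rank deficient; aliased term(s): %s",
            paste(aliased, collapse = ", "))
  p <- length(stats::coef(fit))
  stopIfNot(length(response) > p,
            "need more observations (%d) than parameters (%d)",
            length(response), p)
  ci <- stats::confint(fit, level = 0.95)
  colnames(ci) <- c("low", "high")
  new("LinearModelResult", coefficients = stats::coef(fit), ci95 = ci,
      referenceLevels = refs, n = length(response),
      sigma = summary(fit)$sigma)
}
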