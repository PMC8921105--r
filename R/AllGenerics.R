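#' Cell counts of a cross-tabulation
#'
#' @param x a [CrossTab].
#' @return For `counts`, the 4 x 3 integer matrix of cell counts (ISUP rows,
#'   mG columns).
#' @examples
#' counts(table3CrossTab())
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname counts
#' @export
setMethod("counts", "CrossTab", function(x) x@counts)

#' Risk-table accessors
#'
#' Extract the per-grade proportions and Wilson intervals from a
#' [RiskTable].
#'
#' @param x a [RiskTable].
#' @return `riskGe2` / `riskGe3` return named numeric vectors of proportions
#'   (ISUP >= 2 resp. >= 3 per MRI grade); `ciGe2` / `ciGe3` the matching
#'   3 x 2 interval matrices.
#' @examples
#' riskGe2(riskTable(table3CrossTab()))
#' @export
setGeneric("riskGe2", function(x) standardGeneric("riskGe2"))

#' @rdname riskGe2
#' @export
setGeneric("riskGe3", function(x) standardGeneric("riskGe3"))

#' @rdname riskGe2
#' @export
setGeneric("ciGe2", function(x) standardGeneric("ciGe2"))

#' @rdname riskGe2
#' @export
setGeneric("ciGe3", function(x) standardGeneric("ciGe3"))

#' @rdname riskGe2
setMethod("riskGe2", "RiskTable", function(x) x@riskGe2)

#' @rdname riskGe2
setMethod("riskGe3", "RiskTable", function(x) x@riskGe3)

#' @rdname riskGe2
setMethod("ciGe2", "RiskTable", function(x) x@ciGe2)

#' @rdname riskGe2
setMethod("ciGe3", "RiskTable", function(x) x@ciGe3)

#' Per-group parameter table of a cohort configuration
#'
#' @param x a [CohortConfig].
#' @return The data.frame of per-ISUP distribution parameters (rows
#'   \code{ISUP1..ISUP4}).
#' @examples
#' cohortParams(defaultCohortConfig())[, c("psaMedian", "visibilityProb")]
#' @export
setGeneric("cohortParams", function(x) standardGeneric("cohortParams"))

#' @rdname cohortParams
setMethod("cohortParams", "CohortConfig", function(x) x@params)

#' Value and p value of an association statistic
#'
#' @param x an [AssociationResult].
#' @return `statValue` returns the statistic; `pValue` its (raw) p value,
#'   `NA` when not computed.
#' @examples
#' statValue(kendallTauB(c(1, 2, 3, 4), c(1, 2, 2, 4)))
#' @export
setGeneric("statValue", function(x) standardGeneric("statValue"))

#' @rdname statValue
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname statValue
setMethod("statValue", "AssociationResult", function(x) x@value)

#' @rdname statValue
setMethod("pValue", "AssociationResult", function(x) x@pValue)

#' @describeIn linearModelFit Coefficient estimates of the fit.
#' @param object a [LinearModelResult].
#' @export
setMethod("coef", "LinearModelResult", function(object) object@coefficients)
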