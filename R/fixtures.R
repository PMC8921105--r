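#' Construct a cross-tabulation of ISUP grade groups by MRI grades
#'
#' @param counts numeric 4 x 3 matrix of non-negative integer counts, rows =
#'   ISUP grade groups 1-4 ascending (4 = combined 4-5), columns = MRI
#'   grading groups mG1-mG3 ascending. Dimnames, if absent, are added.
#' @return A validated [CrossTab].
#' @examples
#' crossTab(matrix(c(5, 0, 0,  0, 5, 0,  0, 0, 5,  0, 0, 5),
#'                 nrow = 4, byrow = TRUE))
#' @export
crossTab <- function(counts) {
  counts <- as.matrix(counts)
  stopIfNot(is.numeric(counts) && all(dim(counts) == c(4L, 3L)),
            "counts must be a numeric 4 x 3 matrix")
  stopIfNot(all(is.finite(counts)) && all(counts >= 0) &&
              all(counts == round(counts)),
            "counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("ISUP", .ISUP_LEVELS),
                           paste0("mG", .MG_LEVELS))
  new("CrossTab", counts = counts)
}

#' Published grade-by-ISUP cross-tabulation
#'
#' Returns the packaged study cross-tabulation of MRI grading groups against
#' biopsy ISUP grade groups: 187 graded lesions out of 200 biopsy-confirmed
#' cancers (13 were not visible on mpMRI), with row sums (40, 47, 50, 50),
#' column sums (31, 78, 78).
#'
#' @return A [CrossTab] with the fixed published counts.
#' @examples
#' tab <- table3CrossTab()
#' sum(counts(tab))      # 187 graded lesions
#' riskGe2(riskTable(tab))
#' @export
table3CrossTab <- function() {
  f <- system.file("extdata", "table3_crosstab.csv", package = "mpMRIgrade",
                   mustWork = TRUE)
  d <- utils::read.csv(f, check.names = FALSE)
  crossTab(as.matrix(d[, c("mG1", "mG2", "mG3")]))
}

## T2-conspicuity and PI-RADS category probabilities per ISUP group are not
## part of the published summary tables; these monotone defaults are the
## package's own calibration knobs (see the methods vignette) and can be
## overridden through the CohortConfig.
.T2_DEFAULTS <- matrix(c(0.70, 0.25, 0.05,
                         0.40, 0.35, 0.25,
                         0.20, 0.30, 0.50,
                         0.05, 0.20, 0.75),
                       nrow = 4, byrow = TRUE,
                       dimnames = list(NULL, c("t2Discreet", "t2Overlayed",
                                               "t2Clear")))
.PIRADS_DEFAULTS <- matrix(c(0.45, 0.45, 0.10,
                             0.25, 0.50, 0.25,
                             0.15, 0.45, 0.40,
                             0.05, 0.35, 0.60),
                           nrow = 4, byrow = TRUE,
                           dimnames = list(NULL, c("pirads3", "pirads4",
                                                   "pirads5")))

#' Packaged per-ISUP calibration of the cohort generator
#'
#' Reads the packaged calibration table - the published per-ISUP-group
#' summaries (age mean/SD; medians and quartiles of PSA, PSA density, biopsy
#' infiltration, lesion diameter and ADC per DWI technique; visibility,
#' cross-zonal, cT3 and high-b-value prevalences; zone probabilities derived
#' from the reported per-zone lesion counts) - and completes it with the
#' package's documented defaults for the quantities the study does not
#' report: T2-conspicuity and PI-RADS category probabilities, the rs-EPI
#' acquisition probability (0.40) and the age truncation bounds (40-95
#' years).
#'
#' @return A validated [CohortConfig].
#' @examples
#' cfg <- table2Calibration()
#' cohortParams(cfg)["ISUP1", "visibilityProb"]   # 0.80
#' @export
table2Calibration <- function() {
  f <- system.file("extdata", "table2_calibration.csv",
                   package = "mpMRIgrade", mustWork = TRUE)
  d <- utils::read.csv(f, check.names = FALSE)
  d <- d[order(d$isup), setdiff(colnames(d), "isup")]
  p <- cbind(d,
             as.data.frame(.T2_DEFAULTS),
             as.data.frame(.PIRADS_DEFAULTS))
  rownames(p) <- paste0("ISUP", .ISUP_LEVELS)
  new("CohortConfig", params = p[, .CONFIG_COLS],
      rsEpiProb = 0.40, ageBounds = c(40, 95))
}

#' Default cohort configuration
#'
#' The default calibration driving [generateCohort()]; identical to
#' [table2Calibration()].
#'
#' @return A [CohortConfig].
#' @export
defaultCohortConfig <- function() table2Calibration()

#' Write or read a cohort configuration as CSV
#'
#' `writeCohortConfig()` emits the full per-group parameter table plus the
#' cohort-wide settings so that every calibration knob can be edited by hand
#' and read back with `readCohortConfig()`.
#'
#' @param config a [CohortConfig].
#' @param path file path of the configuration CSV.
#' @return `writeCohortConfig()` returns `path` invisibly;
#'   `readCohortConfig()` returns a validated [CohortConfig].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeCohortConfig(defaultCohortConfig(), f)
#' cfg <- readCohortConfig(f)
#' @export
writeCohortConfig <- function(config, path) {
  stopIfNot(is(config, "CohortConfig"), "config must be a CohortConfig")
  p <- cohortParams(config)
  out <- cbind(isup = .ISUP_LEVELS, p)
  ## cohort-wide settings travel as extra pseudo-rows keyed by isup = NA
  glob <- data.frame(matrix(NA_real_, nrow = 2, ncol = ncol(out),
                            dimnames = list(NULL, colnames(out))))
  glob$isup <- c("rsEpiProb", "ageBounds")
  glob$ageMean <- c(config@rsEpiProb, config@ageBounds[1])
  glob$ageSd <- c(NA_real_, config@ageBounds[2])
  out$isup <- as.character(out$isup)
  utils::write.csv(rbind(out, glob), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortConfig
#' @export
readCohortConfig <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(isup = "character"))
  grp <- d[d$isup %in% as.character(.ISUP_LEVELS), ]
  stopIfNot(nrow(grp) == 4L, "config must contain rows for ISUP 1..4")
  grp <- grp[order(as.integer(grp$isup)), ]
  p <- grp[, .CONFIG_COLS]
  rownames(p) <- paste0("ISUP", .ISUP_LEVELS)
  rs <- d[d$isup == "rsEpiProb", "ageMean"]
  ab <- unlist(d[d$isup == "ageBounds", c("ageMean", "ageSd")],
               use.names = FALSE)
  stopIfNot(length(rs) == 1L && length(ab) == 2L,
            "config must contain rsEpiProb and ageBounds rows")
  new("CohortConfig", params = p, rsEpiProb = as.numeric(rs),
      ageBounds = as.numeric(ab))
}
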