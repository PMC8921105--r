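# Independent oracles and small generators used across the suite.

# O(n^2) brute-force Kendall tau-b by explicit pair enumeration; the
# reference the cell-weighted implementation is checked against.
tauBruteForce <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  S <- sum((sx * sy)[up])
  n0 <- sum(up)
  n1 <- sum(sx[up] == 0)
  n2 <- sum(sy[up] == 0)
  S / sqrt((n0 - n1) * (n0 - n2))
}

# Expand a 4 x 3 count matrix into (ISUP, mG) label vectors.
expandLabels <- function(m) {
  list(isup = rep(rep(1:4, each = 3), as.vector(t(m))),
       mg = rep(rep(1:3, times = 4), as.vector(t(m))))
}

# Random non-degenerate 4 x 3 contingency table (>= 2 non-empty rows and
# columns so tau-b is defined).
randomCrossTabCounts <- function() {
  repeat {
    m <- matrix(rpois(12, 2.5), 4, 3)
    if (sum(rowSums(m) > 0) >= 2 && sum(colSums(m) > 0) >= 2) return(m)
  }
}

# Random visible-lesion cohort rows sweeping the full feature space of the
# grading rule (no clinical fields; classifyCohort only needs these).
randomLesionCohort <- function(n) {
  data.frame(
    patient_id = sprintf("L%06d", seq_len(n)),
    visible = 1L,
    dwi_technique = sample(c("rs_epi", "ss_epi"), n, replace = TRUE),
    adc_um2_s = runif(n, 1, 3999),
    high_b_hyperintense = sample(0:1, n, replace = TRUE),
    t2_conspicuity = sample(c("discreet", "overlayed", "clear"), n,
                            replace = TRUE),
    cross_zonal = sample(0:1, n, replace = TRUE),
    epe = sample(0:1, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

gradeCode <- function(mGrade) match(mGrade, c("mG1", "mG2", "mG3"))
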