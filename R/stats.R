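## Tie-corrected Kendall statistics on a contingency table.
##
## Works on the r x c count matrix in O(r*c) using 2-D prefix sums: for each
## cell, the concordant mass is the count times the total mass strictly
## below-right, the discordant mass the count times the mass strictly
## below-left. Returns S = C - D, the tau-b denominator terms and the
## tie-corrected null variance of S.
.tauFromCounts <- function(m) {
  m <- unname(as.matrix(m))
  r <- nrow(m); c <- ncol(m)
  N <- sum(m)
  P <- matrix(0, r + 1L, c + 1L)
  for (i in seq_len(r)) P[i + 1L, -1L] <- P[i, -1L] + cumsum(m[i, ])
  gt <- lt <- matrix(0, r, c)
  for (i in seq_len(r)) for (j in seq_len(c)) {
    gt[i, j] <- N - P[i + 1L, c + 1L] - P[r + 1L, j + 1L] + P[i + 1L, j + 1L]
    lt[i, j] <- P[r + 1L, j] - P[i + 1L, j]
  }
  C <- sum(m * gt); D <- sum(m * lt)
  rt <- rowSums(m); ct <- colSums(m)
  n0 <- N * (N - 1) / 2
  n1 <- sum(rt * (rt - 1)) / 2
  n2 <- sum(ct * (ct - 1)) / 2
  ## tie-corrected variance of S under independence
  v0 <- N * (N - 1) * (2 * N + 5)
  vt <- sum(rt * (rt - 1) * (2 * rt + 5))
  vu <- sum(ct * (ct - 1) * (2 * ct + 5))
  v1 <- sum(rt * (rt - 1)) * sum(ct * (ct - 1)) / (2 * N * (N - 1))
  v2 <- if (N > 2)
    sum(rt * (rt - 1) * (rt - 2)) * sum(ct * (ct - 1) * (ct - 2)) /
      (9 * N * (N - 1) * (N - 2)) else 0
  list(S = C - D, C = C, D = D, n0 = n0, n1 = n1, n2 = n2, N = N,
       varS = (v0 - vt - vu) / 18 + v1 + v2)
}

.tauResult <- function(parts) {
  denom <- sqrt((parts$n0 - parts$n1) * (parts$n0 - parts$n2))
  stopIfNot(denom > 0,
            "Kendall tau-b is undefined: a margin is constant")
  tau <- parts$S / denom
  p <- if (parts$varS > 0)
    2 * stats::pnorm(-abs(parts$S) / sqrt(parts$varS)) else NA_real_
  new("AssociationResult", statisticName = "kendall_tau_b",
      value = tau, n = as.integer(parts$N), pValue = p)
}

#' Kendall's tau-b with tie correction
#'
#' Rank correlation for ordinal data,
#' \deqn{\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}}}
#' with \eqn{C}/\eqn{D} the concordant/discordant pair counts,
#' \eqn{n_0 = n(n-1)/2} and \eqn{n_1}, \eqn{n_2} the tie terms
#' \eqn{\sum_t t(t-1)/2} over the tie groups of each variable. The p value
#' uses the normal approximation with the standard tie-corrected variance of
#' \eqn{S = C - D} and is therefore approximate. Pairs are counted on the
#' contingency table of the two vectors in \eqn{O(r \cdot c)} cell
#' operations.
#'
#' @param x,y equal-length vectors (ordinal or numeric), \eqn{n \ge 2},
#'   each with at least two distinct values.
#' @return An [AssociationResult] with \code{statisticName}
#'   \code{"kendall_tau_b"}.
#' @examples
#' statValue(kendallTauB(1:4, 1:4))         #  1
#' statValue(kendallTauB(1:4, 4:1))         # -1
#' @export
kendallTauB <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 2L, "need n >= 2")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopIfNot(length(unique(x)) >= 2L && length(unique(y)) >= 2L,
            "Kendall tau-b is undefined for a constant vector")
  .tauResult(.tauFromCounts(table(x, y)))
}

#' @describeIn kendallTauB Cell-weighted form on a [CrossTab]; agrees
#'   exactly with `kendallTauB()` applied to the expanded label pairs.
#' @param table a [CrossTab].
#' @examples
#' statValue(kendallTauBFromTable(table3CrossTab()))   # ~0.475
#' @export
kendallTauBFromTable <- function(table) {
  stopIfNot(is(table, "CrossTab"), "table must be a CrossTab")
  m <- counts(table)
  stopIfNot(sum(m) >= 2, "need at least two observations")
  .tauResult(.tauFromCounts(m))
}

#' Spearman rank correlation on midranks
#'
#' Pearson correlation of the midranks (average ranks for ties) of the two
#' vectors; the p value comes from the t approximation with \eqn{n - 2}
#' degrees of freedom.
#'
#' @param x,y equal-length vectors, \eqn{n \ge 3}, each with at least two
#'   distinct values.
#' @return An [AssociationResult] with \code{statisticName}
#'   \code{"spearman_rho"}.
#' @examples
#' statValue(spearmanRho(c(1, 2, 2, 4), c(2, 3, 3, 9)))   # 1
#' @export
spearmanRho <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopIfNot(n >= 3L, "need n >= 3")
  stopIfNot(length(unique(x)) >= 2L && length(unique(y)) >= 2L,
            "Spearman rho is undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) < 1) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  } else 0
  new("AssociationResult", statisticName = "spearman_rho", value = rho,
      n = as.integer(n), pValue = p)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval; unlike the Wald interval it stays
#' inside \eqn{[0, 1]}, never degenerates at \eqn{k = 0} or \eqn{k = n},
#' and has good small-sample coverage, which is why it backs the risk
#' tables of this package.
#'
#' @param k number of successes, \eqn{0 \le k \le n} (vectorized).
#' @param n number of trials, \eqn{n \ge 1}.
#' @param conf confidence level in (0, 1); default 0.95.
#' @return Matrix with columns \code{low}, \code{high}, one row per
#'   \code{k}.
#' @examples
#' wilsonInterval(0, 10)    # (0, 0.2775)
#' wilsonInterval(14, 31)
#' @export
wilsonInterval <- function(k, n, conf = 0.95) {
  stopIfNot(all(n >= 1) && all(k >= 0) && all(k <= n),
            "need 0 <= k <= n and n >= 1")
  stopIfNot(conf > 0 && conf < 1, "conf must lie in (0, 1)")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Per-grade risk of ISUP >= 2 and >= 3
#'
#' Column-conditional risks of a grade-by-ISUP [CrossTab]: for each MRI
#' grading group, the proportion of lesions with biopsy ISUP grade group
#' >= 2 (clinically significant cancer) and >= 3 (high grade), with Wilson
#' score intervals.
#'
#' @param table a [CrossTab] whose column totals are all positive.
#' @param conf confidence level of the Wilson intervals; default 0.95.
#' @return A [RiskTable].
#' @examples
#' riskTable(table3CrossTab())
#' @export
riskTable <- function(table, conf = 0.95) {
  stopIfNot(is(table, "CrossTab"), "table must be a CrossTab")
  m <- counts(table)
  colTot <- colSums(m)
  empty <- colnames(m)[colTot == 0]
  stopIfNot(length(empty) == 0L,
            "no lesions in grading group(s): %s",
            paste(empty, collapse = ", "))
  kGe2 <- colSums(m[2:4, , drop = FALSE])
  kGe3 <- colSums(m[3:4, , drop = FALSE])
  new("RiskTable", n = setNames(as.integer(colTot), colnames(m)),
      riskGe2 = kGe2 / colTot, riskGe3 = kGe3 / colTot,
      ciGe2 = wilsonInterval(kGe2, colTot, conf),
      ciGe3 = wilsonInterval(kGe3, colTot, conf),
      conf = conf)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA:
#' \eqn{F = MS_{between} / MS_{within}} on \eqn{(k - 1, N - k)} degrees of
#' freedom, with the p value from the F distribution.
#'
#' @param groups list of \eqn{k \ge 2} numeric vectors, each with at least
#'   two values.
#' @return An [AssociationResult] with \code{statisticName}
#'   \code{"anova_F"} and \code{n} the total sample size.
#' @examples
#' oneWayAnova(list(rnorm(20), rnorm(20, 1)))
#' @export
oneWayAnova <- function(groups) {
  stopIfNot(is.list(groups) && length(groups) >= 2L,
            "need at least two groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  stopIfNot(all(lengths(groups) >= 2L),
            "every group needs at least two values")
  k <- length(groups)
  N <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) *
               (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  stopIfNot(msw > 0, "within-group variance is zero")
  f <- msb / msw
  new("AssociationResult", statisticName = "anova_F", value = f,
      n = as.integer(N),
      pValue = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Bonferroni multiplicity correction
#'
#' Family-wise adjustment \eqn{p_{adj} = \min(1, m \, p)} with \eqn{m} the
#' number of tests; delegates to [stats::p.adjust()].
#'
#' @param p vector of raw p values in \eqn{[0, 1]}.
#' @return Adjusted p values, order-preserving and clamped at 1.
#' @examples
#' bonferroniAdjust(c(0.02, 0.5))   # 0.04, 1.00
#' @export
bonferroniAdjust <- function(p) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE),
            "p values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}
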