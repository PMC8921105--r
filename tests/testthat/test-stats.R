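test_that("Kendall tau-b matches its definition on perfect orderings", {
  expect_equal(statValue(kendallTauB(1:4, 1:4)), 1)
  expect_equal(statValue(kendallTauB(1:4, 4:1)), -1)
  expect_error(kendallTauB(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(kendallTauB(1:3, 1:4), "equal length")
})

test_that("tau-b on the published cross-tabulation agrees with independent routes", {
  tab <- table3CrossTab()
  lab <- expandLabels(counts(tab))
  fromTable <- statValue(kendallTauBFromTable(tab))
  fromVectors <- statValue(kendallTauB(lab$isup, lab$mg))
  expect_identical(fromTable, fromVectors)                   # exact
  expect_equal(fromTable, tauBruteForce(lab$isup, lab$mg),
               tolerance = 1e-12)
  expect_equal(fromTable, cor(lab$isup, lab$mg, method = "kendall"),
               tolerance = 1e-12)
  expect_equal(fromTable, 0.4752, tolerance = 1e-4)
  # tie-corrected normal-approximation p agrees with cor.test
  ct <- suppressWarnings(cor.test(lab$isup, lab$mg, method = "kendall"))
  expect_equal(pValue(kendallTauBFromTable(tab)), ct$p.value,
               tolerance = 1e-9)
})

test_that("cell-weighted tau-b equals brute-force pair enumeration on random tables", {
  set.seed(501)
  for (i in 1:100) {
    m <- randomCrossTabCounts()
    lab <- expandLabels(m)
    expect_equal(statValue(kendallTauBFromTable(crossTab(m))),
                 tauBruteForce(lab$isup, lab$mg), tolerance = 1e-12)
  }
})

test_that("pair counting conserves the total number of pairs", {
  core <- getFromNamespace(".tauFromCounts", "mpMRIgrade")
  set.seed(502)
  for (i in 1:25) {
    m <- randomCrossTabCounts()
    parts <- core(m)
    N <- sum(m)
    tiedPairs <- parts$n1 + parts$n2 -
      sum(m * (m - 1) / 2)  # pairs tied in both counted once
    expect_equal(parts$C + parts$D + tiedPairs, N * (N - 1) / 2)
  }
})

test_that("degenerate tables are rejected, concentrated diagonals score 1", {
  solo <- matrix(0L, 4, 3); solo[2, 2] <- 9L
  expect_error(kendallTauBFromTable(crossTab(solo)), "constant")
  diag2 <- matrix(0L, 4, 3); diag2[1, 1] <- 5L; diag2[2, 2] <- 5L
  expect_equal(statValue(kendallTauBFromTable(crossTab(diag2))), 1)
})

test_that("Spearman on midranks agrees with the rank-then-Pearson oracle", {
  expect_equal(statValue(spearmanRho(1:5, 1:5)), 1)
  expect_equal(statValue(spearmanRho(1:5, 5:1)), -1)
  set.seed(503)
  x <- sample(1:4, 60, replace = TRUE)   # heavy ties
  y <- x + sample(0:2, 60, replace = TRUE)
  expect_equal(statValue(spearmanRho(x, y)),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearmanRho(rep(2, 10), 1:10), "constant")
})

test_that("Wilson intervals match the closed form and score-test inversion", {
  expect_equal(wilsonInterval(10, 10)[, "high"], 1, ignore_attr = TRUE)
  expect_equal(wilsonInterval(0, 10)[, "low"], 0, ignore_attr = TRUE)
  expect_equal(wilsonInterval(0, 10)[, "high"], 0.27753, tolerance = 1e-4,
               ignore_attr = TRUE)
  # symmetry under k <-> n - k
  ci <- wilsonInterval(3, 12); ciM <- wilsonInterval(9, 12)
  expect_equal(unname(ci[, "low"]), 1 - unname(ciM[, "high"]),
               tolerance = 1e-12)
  # against prop.test without continuity correction
  for (k in c(1, 7, 14, 30)) {
    pt <- prop.test(k, 31, correct = FALSE)$conf.int
    expect_equal(as.numeric(wilsonInterval(k, 31)), as.numeric(pt),
                 tolerance = 1e-9)
  }
  # width shrinks monotonically in n at fixed k/n
  widths <- sapply(c(10, 40, 160, 640), function(n) {
    ci <- wilsonInterval(0.25 * n, n); ci[, "high"] - ci[, "low"]
  })
  expect_true(all(diff(widths) < 0))
  expect_error(wilsonInterval(5, 4), "k <= n")
})

test_that("risk tables reproduce the published fractions from the fixture", {
  r <- riskTable(table3CrossTab())
  expect_equal(unname(riskGe2(r)), c(14 / 31, 58 / 78, 75 / 78))
  expect_equal(unname(riskGe3(r)), c(4 / 31, 34 / 78, 62 / 78))
  expect_true(all(ciGe2(r)[, 1] <= riskGe2(r) &
                    riskGe2(r) <= ciGe2(r)[, 2]))
  onlyIsup1 <- matrix(0L, 4, 3); onlyIsup1[1, ] <- 1L
  expect_equal(unname(riskGe2(riskTable(crossTab(onlyIsup1)))), rep(0, 3))
  zeroCol <- matrix(1L, 4, 3); zeroCol[, 2] <- 0L
  expect_error(riskTable(crossTab(zeroCol)), "mG2")
})

test_that("risk of ISUP >= 3 never exceeds risk of ISUP >= 2", {
  set.seed(504)
  for (i in 1:50) {
    m <- randomCrossTabCounts()
    if (any(colSums(m) == 0)) next
    r <- riskTable(crossTab(m))
    expect_true(all(riskGe3(r) <= riskGe2(r) + 1e-12))
  }
})

test_that("one-way ANOVA matches the t-test and lm oracles", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(statValue(oneWayAnova(g)), 0)
  set.seed(505)
  a <- rnorm(20); b <- rnorm(25, 0.6)
  tt <- t.test(a, b, var.equal = TRUE)
  res <- oneWayAnova(list(a, b))
  expect_equal(statValue(res), unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(pValue(res), tt$p.value, tolerance = 1e-10)
  # k = 4 groups against anova(lm)
  gr <- lapply(c(0, 0.3, 0.8, 1), function(m) rnorm(15, m))
  y <- unlist(gr); f <- factor(rep(1:4, times = lengths(gr)))
  or <- anova(lm(y ~ f))
  res4 <- oneWayAnova(gr)
  expect_equal(statValue(res4), or[["F value"]][1], tolerance = 1e-10)
  expect_equal(pValue(res4), or[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_error(oneWayAnova(list(1:3)), "two groups")
  expect_error(oneWayAnova(list(1, 1:3)), "two values")
})

test_that("the age contrast of the study design is reliably detected", {
  # four groups with the published age means/SDs at n = 50 per arm
  set.seed(506)
  mu <- c(65, 67, 70, 71); sds <- c(9, 9, 8, 8); n <- 50
  p <- replicate(500, {
    gr <- mapply(function(m, s) rnorm(n, m, s), mu, sds, SIMPLIFY = FALSE)
    pValue(oneWayAnova(gr))
  })
  expect_gte(mean(p < 0.05), 0.90)
  # empirical power at the 0.001 level agrees with the noncentral-F value
  ncp <- n * sum((mu - mean(mu))^2) / mean(sds^2)
  theory <- pf(qf(0.999, 3, 4 * n - 4), 3, 4 * n - 4, ncp = ncp,
               lower.tail = FALSE)
  expect_lt(abs(mean(p < 0.001) - theory), 0.06)
})

test_that("Bonferroni adjustment clamps and preserves order", {
  expect_equal(bonferroniAdjust(0.01), 0.01)
  expect_equal(bonferroniAdjust(c(0.02, 0.5)), c(0.04, 1.0))
  set.seed(507)
  p <- runif(12)
  adj <- bonferroniAdjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in the raw p
  expect_identical(adj, p.adjust(p, "bonferroni"))
  expect_error(bonferroniAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
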