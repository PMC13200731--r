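test_that("pooled t-test matches hand computation and conventions", {
  same <- ttestUnpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)

  a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
  tt <- ttestUnpaired(a, b)  # pooled s^2 = 1/3, df = 6
  expect_equal(tt$statistic, -2.449, tolerance = 1e-3)
  expect_equal(tt$df, 6)
  expect_equal(tt$pValue, 0.0499, tolerance = 1e-2)
  sw <- ttestUnpaired(b, a)
  expect_equal(sw$statistic, -tt$statistic)
  expect_equal(sw$pValue, tt$pValue)
  expect_equal(tt$groupSummaries$a$sem, sd(a) / 2)

  const <- ttestUnpaired(c(1, 1), c(1, 1))
  expect_equal(const$pValue, 1)
  expect_warning(z <- ttestUnpaired(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(z$pValue, 0)
})

test_that("ANOVA + Tukey flags exactly the deviant group", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(11, 12, 13))
  res <- groupCompare(g, "anova_tukey")
  expect_lt(res$pValue, 0.001)
  pw <- res$pairwise
  expect_equal(pw$pAdjusted[pw$pair == "b-a"], 1, tolerance = 1e-6)
  expect_lt(max(pw$pAdjusted[pw$pair %in% c("c-a", "c-b")]), 0.001)
  # oracle: studentized range on the pooled within-group variance
  mse <- 1  # each group has variance 1
  qObs <- abs(mean(g$c) - mean(g$a)) / sqrt(mse / 3)
  expect_equal(pw$pAdjusted[pw$pair == "c-a"],
               ptukey(qObs, 3, 6, lower.tail = FALSE), tolerance = 1e-9)

  ident <- groupCompare(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)),
                        "anova_tukey")
  expect_equal(ident$statistic, 0)
  expect_equal(ident$pValue, 1)
  expect_error(groupCompare(list(a = 1:3, b = 4:6), "anova_tukey"),
               "ttestUnpaired")
})

test_that("Kruskal-Wallis + Dunn handles ties and matches hand-computed z", {
  res <- groupCompare(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)), "kw_dunn")
  # ranks 1..6: mean ranks 1.5/3.5/5.5, s2 = 3.5
  pw <- res$pairwise
  expect_equal(pw$z[pw$pair == "a-b"], -2 / sqrt(3.5), tolerance = 1e-9)
  expect_equal(pw$z[pw$pair == "a-c"], -4 / sqrt(3.5), tolerance = 1e-9)
  expect_equal(pw$pAdjusted[pw$pair == "a-c"],
               min(1, 3 * 2 * pnorm(-4 / sqrt(3.5))), tolerance = 1e-9)

  tied <- groupCompare(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)),
                       "kw_dunn")
  expect_equal(tied$statistic, 0)
})

test_that("Fisher's exact test reproduces the hypertrophic-cell comparison", {
  res <- fisherExact2x2(matrix(c(13, 1, 3, 11), 2))
  expect_equal(round(res$pValue, 4), 3e-04)
  expect_equal(res$pValue, 0.000341, tolerance = 1e-3)
  expect_equal(fisherExact2x2(matrix(5, 2, 2))$pValue, 1)
  expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$pValue, 1 / 3,
               tolerance = 1e-9)
  expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Fisher p equals exhaustive enumeration for small tables", {
  set.seed(5)
  for (i in 1:200) {
    repeat {
      tab <- matrix(rpois(4, 4), 2)
      if (sum(tab) <= 40 && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        break
    }
    expect_equal(fisherExact2x2(tab)$pValue, oracleFisherP(tab),
                 tolerance = 1e-9)
  }
})

test_that("AUC comparison uses per-cell trapezoids then a t-test", {
  cv <- list(x = 0:3, y = c(0, 1, 1, 0))
  expect_equal(aucCompare(list(cv, cv), list(cv, cv))$groupSummaries$A$mean,
               2)
  same <- aucCompare(list(cv, cv), list(cv, cv))
  expect_equal(same$pValue, 1)

  # additivity over concatenated intervals and collinear-point invariance
  y <- function(x) 2 * x + 1
  full <- list(x = c(0, 2, 4), y = y(c(0, 2, 4)))
  dense <- list(x = c(0, 1, 2, 3, 4), y = y(c(0, 1, 2, 3, 4)))
  g2 <- list(list(x = c(0, 1), y = c(5, 5)), list(x = c(0, 1), y = c(4, 4)))
  aucFull <- aucCompare(list(full, full), g2)$groupSummaries$A$mean
  aucDense <- aucCompare(list(dense, dense), g2)$groupSummaries$A$mean
  expect_equal(aucFull, aucDense, tolerance = 1e-12)

  bad <- list(list(x = 0:2, y = 1:3), list(x = c(0, 1, 3), y = 1:3))
  expect_error(aucCompare(bad, g2), "x grid")

  # synthetic Sholl curves: extra branching raises the AUC
  mkCurve <- function(tr) {
    sh <- shollAnalysis(tr)
    list(x = seq(0.1, 1, by = 0.1), y = sh$normalized)
  }
  ctrl <- lapply(1:6, function(s) mkCurve(genArbor(seed = 300 + s)))
  ko <- lapply(1:6, function(s) mkCurve(genArbor("pten_ko", seed = 400 + s)))
  cmp <- aucCompare(ko, ctrl)
  expect_gt(cmp$groupSummaries$A$mean, cmp$groupSummaries$B$mean)
})

test_that("ROI normalization modes", {
  expect_equal(roiNormalize(2, 1, "ratio"), 2)
  expect_equal(roiNormalize(1.5, 1.5, "ratio"), 1)  # no-enrichment baseline
  expect_equal(roiNormalize(5, 2, "subtract"), 3)
  expect_equal(roiNormalize(1, 2, "subtract"), -1)  # reported as-is
  expect_error(roiNormalize(1, 0, "ratio"), "positive")
})

test_that("type-I error is nominal under the null", {
  set.seed(17)
  pT <- replicate(2000, ttestUnpaired(rnorm(8), rnorm(8))$pValue)
  expect_equal(mean(pT < 0.05), 0.05, tolerance = 0.02 / 0.05)
  pA <- replicate(600, groupCompare(list(a = rnorm(6), b = rnorm(6),
                                         c = rnorm(6)),
                                    "anova_tukey")$pValue)
  expect_equal(mean(pA < 0.05), 0.05, tolerance = 0.025 / 0.05)
})
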