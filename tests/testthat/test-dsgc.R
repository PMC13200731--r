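# convenience: a UnitResponse from deterministic per-direction counts
unitFromTuning <- function(tuning, nEpochs = 1, id = "u") {
  UnitResponse(id, matrix(rep(round(tuning), each = nEpochs), nEpochs, 12))
}

test_that("mean tuning is the per-direction mean with a spike total", {
  u <- UnitResponse("u", matrix(3, 2, 12))
  mt <- meanTuning(u)
  expect_equal(mt$tuning, rep(3, 12))
  expect_equal(mt$totalSpikes, 72)
  one <- UnitResponse("u", matrix(0:11, 1, 12))
  expect_equal(meanTuning(one)$tuning, as.numeric(0:11))
  zero <- UnitResponse("u", matrix(0, 3, 12))
  expect_equal(meanTuning(zero)$totalSpikes, 0)
})

test_that("DSI analytics: uniform, single-direction, and von Mises tuning", {
  expect_equal(computeDSI(rep(5, 12)), 0)
  expect_equal(computeDSI(c(9, rep(0, 11))), 1)
  th <- seq(0, 330, by = 30) * pi / 180
  vmTuning <- exp(2 * cos(th))
  # 12-point periodic sampling of exp(kappa cos) gives the Bessel ratio
  # I1(2)/I0(2) almost exactly
  expect_equal(computeDSI(vmTuning), besselI(2, 1) / besselI(2, 0),
               tolerance = 1e-3 / 0.6977)
  expect_equal(computeDSI(vmTuning), 0.6977, tolerance = 1e-3 / 0.6977)
  expect_error(computeDSI(rep(0, 12)), "all-zero")
})

test_that("DSI is scale invariant, rotation equivariant and reversal-symmetric", {
  set.seed(7)
  for (i in 1:5) {
    tuning <- rgamma(12, 2, 1)
    d0 <- computeDSI(tuning)
    expect_equal(computeDSI(37.5 * tuning), d0, tolerance = 1e-12)
    rot <- tuning[c(4:12, 1:3)]  # rotate by 90 degrees
    expect_equal(computeDSI(rot), d0, tolerance = 1e-12)
    rev12 <- tuning[c(1, 12:2)]  # theta -> -theta
    expect_equal(computeDSI(rev12), d0, tolerance = 1e-12)
    expect_gte(d0, 0); expect_lte(d0, 1)
  }
})

test_that("von Mises fit recovers exact-model parameters", {
  th <- seq(0, 330, by = 30) * pi / 180
  tuning <- 1 + 20 * exp(2 * (cos(th - pi / 2) - 1))
  fit <- fitVonMises(tuning)
  expect_lt(circularGapDeg(fit$mu, 90), 1)
  expect_lt(abs(fit$kappa - 2) / 2, 0.02)
  expect_equal(fit$amplitude, 20, tolerance = 0.02)
  expect_equal(fit$baseline, 1, tolerance = 0.05)
  expect_gt(fit$vmFit, 0.999)
})

test_that("flat tuning yields the undefined-fit sentinel", {
  expect_warning(fit <- fitVonMises(rep(4, 12)), "flat tuning")
  expect_identical(fit$vmFit, -Inf)
})

test_that("fit recovers parameters from noisy Poisson units", {
  ok <- vapply(1:20, function(s) {
    u <- genUnitResponses(nUnits = 1, dsFraction = 1, kappa = 2,
                          meanPreferredSpikes = 20, baselineSpikes = 2,
                          nEpochs = 30, seed = 4000 + s)[[1]]
    fit <- suppressWarnings(fitVonMises(meanTuning(u)$tuning))
    truth <- u@meta$preferredDeg
    circularGapDeg(fit$mu, truth) <= 5 && abs(fit$kappa - 2) / 2 <= 0.2
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("FWHM closed forms", {
  expect_equal(tuningWidthFWHM(log(2)), 180)
  expect_equal(tuningWidthFWHM(2), 98.399, tolerance = 0.01 / 98.399)
  expect_lt(tuningWidthFWHM(1e6), 0.2)      # kappa -> Inf: width -> 0
  expect_equal(tuningWidthFWHM(0.2), 360)   # wider than the circle
  expect_equal(tuningWidthFWHM(0), 360)
  expect_error(tuningWidthFWHM(-1), ">= 0")
})

test_that("DSGC classification applies the four filters in order", {
  th <- seq(0, 330, by = 30) * pi / 180
  shape <- exp(2 * (cos(th - pi / 2) - 1))

  # strong tuning but only 399 spikes in total
  weak <- round(399 * shape / sum(shape))
  weak[which.max(weak)] <- weak[which.max(weak)] + (399 - sum(weak))
  r <- classifyDSGC(unitFromTuning(weak))
  expect_false(r@isDSGC)
  expect_false(r@filters[["spikes"]])
  expect_equal(r@totalSpikes, 399)

  # plenty of spikes, clean fit, but DSI below threshold (kappa = 0.6
  # gives DSI ~ I1/I0 = 0.29)
  lowdsi <- 60 * exp(0.6 * (cos(th) - 1))
  u <- UnitResponse("u", matrix(rep(round(lowdsi), each = 2), 2, 12))
  r <- classifyDSGC(u)
  expect_false(r@isDSGC)
  expect_false(r@filters[["dsi"]])
  expect_lt(r@dsi, 0.37)
  expect_gt(r@vmFit, 0.5)
  expect_true(r@filters[["spikes"]])

  # passes everything
  good <- 1 + 30 * exp(2 * (cos(th - pi / 3) - 1))
  u <- UnitResponse("u", matrix(rep(round(good), each = 5), 5, 12))
  r <- classifyDSGC(u)
  expect_true(r@isDSGC)
  expect_true(all(r@filters))
  expect_gte(r@preferredMeanSpikes, 10)
  expect_equal(r@vmMu, 60, tolerance = 3)

  # preferred-direction filter: same shape scaled so the preferred mean
  # falls below 10 spikes, with the spike total topped up by many epochs
  faint <- 0.2 + 6 * exp(2 * (cos(th - pi / 3) - 1))
  u <- UnitResponse("u", matrix(rep(round(faint), each = 40), 40, 12))
  r <- classifyDSGC(u)
  expect_true(r@filters[["spikes"]])
  expect_false(r@filters[["preferred"]])
  expect_false(r@isDSGC)
})

test_that("classification separates DS from non-DS simulated populations", {
  units <- genUnitResponses(nUnits = 80, dsFraction = 0.2, seed = 31)
  tab <- dsgcTable(units)
  truth <- vapply(units, function(u) isTRUE(u@meta$ds), logical(1))
  expect_lt(mean(tab$isDSGC[!truth]), 0.05)
  expect_gt(mean(tab$isDSGC[truth]), 0.8)
  expect_gt(mean(tab$dsi[tab$isDSGC]), mean(tab$dsi[!tab$isDSGC]))
})
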