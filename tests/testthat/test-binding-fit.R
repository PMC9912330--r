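test_that("fractional shift matches the mass-action oracle on a grid", {
  alphas <- c(0.01, 0.1, 0.5, 1, 2, 5, 20)
  betas <- c(1e-6, 1e-3, 0.05, 1, 10, 100)
  for (a in alphas) for (b in betas)
    expect_equal(fractionalShift(a, b), massActionF(a, b),
                 tolerance = 1e-10)
  # hand value: alpha = beta = 1
  expect_equal(fractionalShift(1, 1), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
})

test_that("fractional shift limits and monotonicity hold", {
  b <- 10^seq(-8, 2, length.out = 25)
  expect_true(all(fractionalShift(0, b) == 0))
  expect_lt(1 - fractionalShift(1e8, 0.05), 1e-6)
  # stoichiometric regime
  a <- seq(0, 3, by = 0.05)
  expect_equal(fractionalShift(a, 1e-16), pmin(a, 1), tolerance = 1e-8)
  # numerically stable for tiny beta
  expect_true(all(is.finite(fractionalShift(a, 1e-8))))
  # monotone non-decreasing in alpha, non-increasing in beta, in [0,1]
  g <- expand.grid(a = seq(0, 20, length.out = 41),
                   b = 10^seq(-6, 2, length.out = 25))
  f <- fractionalShift(g$a, g$b)
  expect_true(all(f >= 0 & f <= 1 + 1e-15))
  fm <- matrix(f, nrow = 41)
  expect_true(all(apply(fm, 2, diff) >= -1e-12))
  expect_true(all(apply(fm, 1, diff) <= 1e-12))
  # weak-binding limit: f * beta / alpha -> 1 as beta -> Inf
  expect_equal(fractionalShift(2, 1e8) * 1e8 / 2, 1, tolerance = 1e-6)
  expect_error(fractionalShift(-1, 1), "alpha")
  expect_error(fractionalShift(1, 0), "betaD")
})

test_that("TSP calibration maps endpoints and midpoint correctly", {
  cal <- alphaCalFromEndpoints(iA = 10, iB = 0.5, alphaMax = 5)
  expect_equal(alphaFromTsp(10, cal$slope, cal$intercept), 0)
  expect_equal(alphaFromTsp(0.5, cal$slope, cal$intercept), 5)
  expect_equal(alphaFromTsp(5.25, cal$slope, cal$intercept), 2.5)
  expect_error(alphaCalFromEndpoints(3, 3, 5), "degenerate")
})

test_that("noiseless global fit recovers K_D, slope and intercept exactly", {
  fx <- makeFixtureHfyn(seed = 1, noise = noiselessModel(1),
                        exactVolumes = TRUE)
  csp <- buildCspTable(fx$series)
  fit <- globalFit(csp, fx$series, proteinConc = 1000)
  expect_true(fit@converged)
  expect_equal(betaD(fit), 0.048, tolerance = 1e-6)
  expect_equal(kD(fit), 48, tolerance = 1e-6)
  # true calibration: alpha and I_TSP are both affine in the mixing
  # fraction x: alpha = 5x, I = 10 - 9.5x
  expect_equal(fit@calSlope, -5 / 9.5, tolerance = 1e-6)
  expect_equal(fit@calIntercept, 50 / 9.5, tolerance = 1e-6)
  # zero-residual limit: interval width collapses
  expect_lt(diff(fit@ci95["kD", c("lower", "upper")]), 1e-6)
})

test_that("fitting the calibration or supplying alpha gives the same K_D", {
  fx <- makeFixtureHfyn(seed = 2, noise = noiselessModel(2),
                        exactVolumes = TRUE)
  csp <- buildCspTable(fx$series)
  fit1 <- globalFit(csp, fx$series, proteinConc = 1000)
  fit2 <- globalFit(csp, fx$series, proteinConc = 1000,
                    alphaKnown = fx$groundTruth$alpha)
  expect_equal(kD(fit1), kD(fit2), tolerance = 1e-6)
  expect_equal(kD(fit2), 48, tolerance = 1e-6)
})

test_that("the 95% interval covers the generating K_D at default noise", {
  fx <- makeFixtureHfyn(seed = 1)
  csp <- buildCspTable(fx$series)
  fit <- globalFit(csp, fx$series, proteinConc = 1000)
  expect_true(fit@converged)
  ci <- fit@ci95["kD", ]
  expect_lte(ci[["lower"]], 48)
  expect_gte(ci[["upper"]], 48)
  expect_lte(ci[["lower"]], kD(fit))
  expect_gte(ci[["upper"]], kD(fit))
  # the model has no per-residue shape freedom: no residue's residual
  # spread should stand far out of the ensemble
  rms <- tapply(fit@residuals$residual, fit@residuals$label,
                function(r) sqrt(mean(r^2)))
  expect_lt(max(rms), 4 * sqrt(mean(fit@residuals$residual^2)))
})

test_that("interval width scales with the noise level and with the level argument", {
  width <- function(noiseScale) {
    mean(vapply(1:20, function(s) {
      fx <- makeFixtureHfyn(seed = s, noise = NoiseModel(
        shiftNoiseH = 0.001 * noiseScale, shiftNoiseN = 0.01 * noiseScale,
        intensityRelNoise = 0, seed = s))
      csp <- buildCspTable(fx$series)
      fit <- globalFit(csp, fx$series, proteinConc = 1000)
      diff(fit@ci95["kD", c("lower", "upper")])
    }, numeric(1)))
  }
  r <- width(2) / width(1)
  expect_gt(r, 1.5)
  expect_lt(r, 2.8)

  fx <- makeFixtureHfyn(seed = 3)
  csp <- buildCspTable(fx$series)
  fit <- globalFit(csp, fx$series, proteinConc = 1000)
  ci0 <- confidenceIntervals(fit, level = 0)
  expect_equal(ci0[, "lower"], ci0[, "estimate"])
  expect_equal(ci0[, "upper"], ci0[, "estimate"])
  ci95 <- confidenceIntervals(fit, level = 0.95)
  expect_equal(ci95["kD", ], fit@ci95["kD", ], tolerance = 1e-9)
  ci50 <- confidenceIntervals(fit, level = 0.5)
  expect_lt(diff(ci50["kD", c("lower", "upper")]),
            diff(ci95["kD", c("lower", "upper")]))
})

test_that("the residue-cluster bootstrap interval brackets the estimate", {
  fx <- makeFixtureHfyn(seed = 5)
  csp <- buildCspTable(fx$series)
  fit <- globalFit(csp, fx$series, proteinConc = 1000,
                   ciMethod = "bootstrap", nBoot = 60, bootSeed = 5)
  ci <- fit@ci95["kD", ]
  expect_lte(ci[["lower"]], kD(fit))
  expect_gte(ci[["upper"]], kD(fit))
  expect_gt(diff(ci[c("lower", "upper")]), 0)
})

test_that("degenerate fit inputs are rejected informatively", {
  fx <- makeFixtureHfyn(seed = 1)
  csp <- buildCspTable(fx$series)
  short <- TitrationSeries(0:2, fx$series@peakLists[1:3],
                           iTSP(fx$series)[1:3])
  expect_error(globalFit(csp, short, 1000), "at least 4")
  expect_error(globalFit(csp, fx$series, 1000,
                         exclude = significantLabels(csp)),
               "no significant residues")
  expect_error(globalFit(csp, fx$series, proteinConc = -5), "proteinConc")
})
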