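test_that("displacement mixing follows the closed-form recursion", {
  chip <- ChipParams(circuitVolume = 10, injectionVolumeMean = 2,
                     injectionVolumeSd = 0, nSteps = 50L,
                     proteinConc = 1000, ligandConcB = 1000)
  sched <- simulateMixingSchedule(chip, noiselessModel())
  n <- 0:50
  expect_equal(sched@schedule$ligandConc / 1000, 1 - (1 - 0.2)^n,
               tolerance = 1e-12)
  # fixed point: the circuit converges on solution b
  expect_lt(abs(sched@schedule$ligandConc[51] - 1000), 1000 * 1e-4)
  # mass balance: alpha tracks ligand exactly, protein constant
  expect_equal(alphaValues(sched), sched@schedule$ligandConc / 1000)
  expect_identical(sched@proteinConc, 1000)
})

test_that("random injection volumes are truncated, reproducible, and mix monotonically", {
  chip <- ChipParams(nSteps = 10L)
  s1 <- simulateMixingSchedule(chip, NoiseModel(seed = 42))
  s2 <- simulateMixingSchedule(chip, NoiseModel(seed = 42))
  s3 <- simulateMixingSchedule(chip, NoiseModel(seed = 43))
  expect_identical(s1@schedule, s2@schedule)
  expect_false(identical(s1@schedule$injectedVolume,
                         s3@schedule$injectedVolume))
  v <- s1@schedule$injectedVolume[-1]
  expect_true(all(v > 0 & v < chip@circuitVolume))
  expect_true(all(diff(s1@schedule$ligandConc) >= 0))
})

test_that("invalid chip parameters are rejected", {
  expect_error(ChipParams(injectionVolumeMean = 12, circuitVolume = 10),
               "smaller than circuitVolume")
  expect_error(ChipParams(tspConcA = 10, tspConcB = 5),
               "order of magnitude")
  expect_error(ChipParams(circuitVolume = -1), "circuitVolume")
})

test_that("TSP concentration is affine in alpha with zero residual", {
  chip <- ChipParams(nSteps = 10L)
  sched <- simulateMixingSchedule(chip, NoiseModel(seed = 5))
  fitlm <- stats::lm(tspConc ~ alpha, data = sched@schedule)
  expect_lt(max(abs(stats::residuals(fitlm))), 1e-10)
})

test_that("noiseless peaks sit at free positions without ligand and at saturation with it", {
  prot <- proteinDef(c("A1", "G2", "W3"), c(8.1, 8.5, 9.9),
                     c(120, 110, 129), ddMaxH = c(0.2, 0, -0.1),
                     ddMaxN = c(1, 0, -2))
  chipNoLig <- ChipParams(injectionVolumeSd = 0, ligandConcB = 0)
  schedNoLig <- simulateMixingSchedule(chipNoLig, noiselessModel())
  ser <- generatePeakLists(prot, schedNoLig, betaD = 0.05,
                           noise = noiselessModel())
  for (i in seq_len(nSteps(ser)))
    expect_equal(peakList(ser, i)$deltaH, prot$deltaH0, tolerance = 1e-12)

  # stoichiometric limit: beta_D -> 0 with final alpha > 1
  chip <- ChipParams(injectionVolumeSd = 0)
  sched <- simulateMixingSchedule(chip, noiselessModel())
  ser2 <- generatePeakLists(prot, sched, betaD = 1e-12,
                            noise = noiselessModel())
  last <- peakList(ser2, nSteps(ser2))
  expect_equal(last$deltaH, prot$deltaH0 + prot$ddMaxH, tolerance = 1e-6)
  expect_equal(last$deltaN, prot$deltaN0 + prot$ddMaxN, tolerance = 1e-6)
})

test_that("noiseless trajectories are exactly collinear", {
  fx <- makeFixtureHfyn(seed = 3, noise = noiselessModel(3))
  tr <- trackPeaks(fx$series)
  moving <- names(which(fx$groundTruth$ddMaxWeighted > 0))
  for (lab in moving) {
    i <- match(lab, tr$label)
    expect_lt(linearityCheck(tr$deltaH[i, ], tr$deltaN[i, ]), 1e-12)
  }
})

test_that("hFyn fixture has 59 amides, 12 perturbed, and is deterministic", {
  fx <- makeFixtureHfyn(seed = 7)
  expect_identical(nrow(fx$protein), 59L)
  expect_identical(length(unique(fx$protein$label)), 59L)
  perturbed <- fx$groundTruth$perturbedLabels
  expect_identical(length(perturbed), 12L)
  nums <- parseResidueLabel(perturbed)$number
  expect_true(all(nums %in% c(96:100, 117:120, 135:137)))
  expect_identical(fx$groundTruth$alpha[1], 0)
  # same seed twice: byte-identical series
  fx2 <- makeFixtureHfyn(seed = 7)
  expect_identical(fx$series, fx2$series)
  expect_false(identical(fx$series, makeFixtureHfyn(seed = 8)$series))
  # 11-point series starting at the protein-only reference
  expect_identical(nSteps(fx$series), 11L)
})
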