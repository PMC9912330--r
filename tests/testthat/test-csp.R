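test_that("weighted CSP matches hand arithmetic and is symmetric", {
  expect_identical(computeCsp(8.2, 119, 8.2, 119), 0)
  # single-axis case: weight irrelevant
  expect_equal(computeCsp(8.0, 119, 8.05, 119, nWeight = 0.7), 0.05)
  expect_equal(computeCsp(8.0, 119, 8.1, 119.5),
               sqrt(0.1^2 + (0.14 * 0.5)^2))
  expect_equal(computeCsp(8.0, 119, 8.1, 119.5, nWeight = 0.14),
               0.1220655, tolerance = 1e-6)
  # direction symmetry
  expect_equal(computeCsp(8.0, 119, 8.1, 119.5),
               computeCsp(8.1, 119.5, 8.0, 119))
  expect_error(computeCsp(8, 119, 8.1, 119.5, nWeight = 0), "nWeight")
})

test_that("sigma_c iteration reproduces the worked example", {
  vals <- c(rep(0.01, 10), 1.0)
  r <- significanceThreshold(vals)
  # first pass: sd about zero ~ 0.302, 1.0 > 3 sigma and is excluded;
  # retained set of ten 0.01s gives sigma_c = 0.01
  expect_equal(sqrt(mean(vals^2)), 0.3017, tolerance = 1e-3)
  expect_equal(sigmaC(r), 0.01)
  expect_identical(r@excluded, 11L)
  expect_identical(r@iterations, 2L)
  expect_identical(which(r@significant), 11L)
})

test_that("sigma_c boundary is exclusive and degenerate inputs work", {
  r <- significanceThreshold(rep(0.05, 6))
  expect_equal(sigmaC(r), 0.05)
  expect_false(any(r@significant))
  r0 <- significanceThreshold(rep(0, 5))
  expect_identical(sigmaC(r0), 0)
  expect_false(any(r0@significant))
  expect_error(significanceThreshold(c(0.1, 0.2)), "at least 3")
  expect_error(significanceThreshold(c(0.1, -0.2, 0.3)), "non-negative")
})

test_that("sigma_c is permutation invariant and scales linearly", {
  set.seed(11)
  for (rep in 1:5) {
    vals <- c(abs(rnorm(20, 0, 0.01)), runif(3, 0.1, 0.3))
    r <- significanceThreshold(vals)
    p <- sample(length(vals))
    rp <- significanceThreshold(vals[p])
    expect_equal(sigmaC(rp), sigmaC(r))
    expect_identical(rp@significant, r@significant[p])
    # scaling by c > 0 scales sigma_c and keeps the selection
    rs <- significanceThreshold(vals * 7.3)
    expect_equal(sigmaC(rs), sigmaC(r) * 7.3)
    expect_identical(rs@significant, r@significant)
  }
})

test_that("the iterative exclusion agrees with brute force over all orders", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    vals <- round(c(abs(rnorm(n - 1, 0, 0.02)), runif(1, 0, 0.5)), 4)
    all_orders <- sigmaCAllOrders(vals)
    expect_length(all_orders, 1)
    expect_equal(signif(sigmaC(significanceThreshold(vals)), 12),
                 all_orders)
  }
})

test_that("label tracking matches ground truth on the fixture", {
  fx <- makeFixtureHfyn(seed = 4, noise = noiselessModel(4))
  trL <- trackPeaks(fx$series, "by_label")
  expect_identical(trL$label, fx$protein$label)
  expect_false(any(is.na(trL$deltaH)))
  expect_equal(unname(trL$deltaH[, 1]), fx$protein$deltaH0)
})

test_that("nearest-neighbour linking agrees with label matching on a sparse spectrum", {
  # well-separated peaks; the link tolerance covers the largest
  # step-to-step jump, so nearest matching must reconstruct the same
  # trajectories as label identity
  prot <- proteinDef(paste0("A", 1:5),
                     deltaH0 = c(7.0, 7.8, 8.6, 9.4, 10.2),
                     deltaN0 = c(105, 112, 119, 126, 133),
                     ddMaxH = c(0.15, 0, -0.12, 0.2, 0),
                     ddMaxN = c(1.5, 0, 0.9, -1.2, 0))
  sched <- simulateMixingSchedule(ChipParams(injectionVolumeSd = 0),
                                  noiselessModel())
  ser <- generatePeakLists(prot, sched, 0.048, noiselessModel())
  trL <- trackPeaks(ser, "by_label", tolH = 0.2, tolN = 2)
  trN <- trackPeaks(ser, "nearest", tolH = 0.2, tolN = 2)
  expect_equal(trN$deltaH, trL$deltaH, tolerance = 1e-12)
  expect_equal(trN$deltaN, trL$deltaN, tolerance = 1e-12)
  expect_false(any(trN$ambiguous))
})

test_that("peaks closer than the tolerance are overlap-flagged", {
  prot <- proteinDef(c("A1", "G2", "F3"),
                     deltaH0 = c(8.000, 8.005, 9.5),
                     deltaN0 = c(120.000, 120.005, 112),
                     ddMaxH = c(0, 0, 0.1), ddMaxN = c(0, 0, 1))
  sched <- simulateMixingSchedule(ChipParams(injectionVolumeSd = 0),
                                  noiselessModel())
  ser <- generatePeakLists(prot, sched, 0.05, noiselessModel())
  tr <- trackPeaks(ser, tolH = 0.02, tolN = 0.2)
  expect_identical(unname(tr$overlap), c(TRUE, TRUE, FALSE))
})

test_that("linearity score detects a bent trajectory", {
  h <- seq(8.0, 8.1, length.out = 7)
  n <- seq(120, 121, length.out = 7)
  expect_lt(linearityCheck(h, n), 1e-12)
  h2 <- h; h2[4] <- h2[4] + 0.05
  # brute-force perpendicular distance bound: the bend must score at
  # least ~half its offset even after the line re-balances
  expect_gte(linearityCheck(h2, n), 0.01)
  expect_error(linearityCheck(c(8, 8.1), c(120, 121)), "3 points")
})

test_that("the CSP table composes tracking, CSPs and significance", {
  fx <- makeFixtureHfyn(seed = 1)
  csp <- buildCspTable(fx$series)
  expect_identical(length(csp@label), 59L)
  expect_true(all(csp@dd[, 1] == 0))
  expect_true(all(csp@dd >= 0))
  expect_equal(unname(ddMax(csp)), unname(csp@dd[, 11]))
  # saturated by construction: alpha_end >> 1 + beta_D
  expect_lt(csp@saturationDiagnostic, 2 * 0.02)
  sig <- significantLabels(csp)
  expect_setequal(sig, fx$groundTruth$perturbedLabels)
})

test_that("noiseless significant set equals the ground-truth perturbed set", {
  for (s in c(2, 9)) {
    fx <- makeFixtureHfyn(seed = s, noise = noiselessModel(s))
    csp <- buildCspTable(fx$series)
    expect_setequal(significantLabels(csp), fx$groundTruth$perturbedLabels)
  }
})

test_that("an overlapping pair is flagged and excluded from the fit", {
  fx <- makeFixtureHfyn(seed = 1, overlapPair = TRUE)
  csp <- buildCspTable(fx$series)
  expect_true(all(c("E98", "Y132") %in% overlapLabels(csp)))
  fit <- globalFit(csp, fx$series, proteinConc = 1000)
  expect_false("E98" %in% fit@labelsUsed)
})
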