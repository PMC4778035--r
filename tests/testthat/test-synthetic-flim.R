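test_that("zero lifetime gives an unshifted full-modulation cosine", {
  gt <- flimGroundTruth(matrix(0, 3, 3), intensityMap = 100)
  stk <- simulateFlimStack(gt)
  k <- 0:11
  expected <- 100 * (1 + cos(2 * pi * k / 12))
  expect_equal(as.numeric(stk@images[1, 1, ]), expected)
})

test_that("the fluorescein lifetime is encoded as atan(w tau)", {
  gt <- fluoresceinTruth(4, 4)
  stk <- simulateFlimStack(gt)
  est <- fitPhaseModulation(stk)
  phiExpected <- atan(2 * pi * 4e7 * 4e-9)
  expect_equal(est$phi[2, 2], phiExpected, tolerance = 1e-10)
})

test_that("photon-noise stacks are reproducible under a fixed seed", {
  gt <- flimGroundTruth(matrix(2.5, 6, 6), intensityMap = 500)
  a <- simulateFlimStack(gt, photonNoise = TRUE, seed = 21)
  b <- simulateFlimStack(gt, photonNoise = TRUE, seed = 21)
  expect_identical(a@images, b@images)
  c <- simulateFlimStack(gt, photonNoise = TRUE, seed = 22)
  expect_false(identical(a@images, c@images))
})

test_that("FRET mixture phasor interpolates between component lifetimes", {
  ph0 <- fretMixturePhasor(2.381, 1.2, 0)
  expect_equal(ph0$tauPhi, 2.381, tolerance = 1e-12)
  ph1 <- fretMixturePhasor(2.381, 1.2, 1)
  expect_equal(ph1$tauPhi, 1.2, tolerance = 1e-12)
  phm <- fretMixturePhasor(2.381, 1.2, 0.4)
  expect_gt(phm$tauPhi, 1.2)
  expect_lt(phm$tauPhi, 2.381)
  ## calibration inverts the mixture exactly
  f <- calibrateFretFraction(2.381, 1.2, 2.254)
  expect_equal(fretMixturePhasor(2.381, 1.2, f)$tauPhi, 2.254,
               tolerance = 1e-9)
})

test_that("ground-truth validity is enforced", {
  expect_error(flimGroundTruth(matrix(-1, 2, 2)), ">= 0")
  expect_error(flimGroundTruth(matrix(1, 2, 2), nPhases = 2L), "nPhases")
})
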