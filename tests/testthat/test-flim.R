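test_that("phase fitting is exact on noiseless cosines", {
  ## unshifted cosine with m = 1
  stk <- simulateFlimStack(flimGroundTruth(matrix(0, 3, 3),
                                           intensityMap = 200))
  est <- fitPhaseModulation(stk)
  expect_equal(est$phi[1, 1], 0, tolerance = 1e-12)
  expect_equal(est$m[1, 1], 1, tolerance = 1e-12)
  ## shifting the stack by one phase step shifts phi by 2 pi / 12
  shifted <- stk
  shifted@images <- stk@images[, , c(12, 1:11)]
  estS <- fitPhaseModulation(shifted)
  expect_equal(estS$phi[2, 2], 2 * pi / 12, tolerance = 1e-12)
  ## forward-model inversion at tau = 2.5 ns
  stk25 <- simulateFlimStack(flimGroundTruth(matrix(2.5, 4, 4)))
  est25 <- fitPhaseModulation(stk25)
  expect_equal(est25$phi[3, 3], atan(2 * pi * 4e7 * 2.5e-9),
               tolerance = 1e-6)
})

test_that("non-positive mean intensity masks the pixel", {
  imgs <- array(1, c(2, 2, 12))
  imgs[1, 1, ] <- 0
  est <- fitPhaseModulation(phaseStack(imgs))
  expect_false(est$valid[1, 1])
  expect_true(est$valid[2, 2])
})

test_that("lifetime round-trip is exact to 1e-3 ns across the range", {
  taus <- c(0.5, 1, 2, 2.381, 3, 4, 5)
  gt <- flimGroundTruth(matrix(taus, 1), intensityMap = 1000)
  stk <- simulateFlimStack(gt, instrumentPhase = 0.4, instrumentMod = 0.85)
  ref <- simulateFlimStack(fluoresceinTruth(4, 4), instrumentPhase = 0.4,
                           instrumentMod = 0.85)
  map <- computeLifetimeMap(stk, ref)
  expect_true(all(map@valid))
  expect_equal(as.numeric(map@tauPhi), taus, tolerance = 1e-3)
  ## modulation lifetime agrees for mono-exponential pixels
  expect_equal(as.numeric(map@tauMod), taus, tolerance = 1e-3)
})

test_that("the fluorescein reference measures itself at 4.00 ns", {
  ref <- simulateFlimStack(fluoresceinTruth(8, 8), instrumentPhase = 0.3)
  map <- computeLifetimeMap(ref, ref)
  expect_equal(mean(map@tauPhi[map@valid]), 4.00, tolerance = 1e-9)
})

test_that("referencing is required and zero phase maps to zero lifetime", {
  stk <- simulateFlimStack(flimGroundTruth(matrix(2, 2, 2)))
  est <- fitPhaseModulation(stk)
  expect_error(lifetimeFromPhase(est, stk), "reference")
  gt0 <- flimGroundTruth(matrix(0, 2, 2), intensityMap = 500)
  stk0 <- simulateFlimStack(gt0)
  ref0 <- simulateFlimStack(flimGroundTruth(matrix(0, 2, 2),
                                            intensityMap = 500,
                                            referenceLifetime = 0))
  stk0@referenceLifetime <- 0
  map0 <- computeLifetimeMap(stk0, ref0)
  expect_equal(as.numeric(map0@tauPhi), rep(0, 4), tolerance = 1e-9)
})

test_that("lifetimes are insensitive to a 2 pi shift of all phases", {
  gt <- flimGroundTruth(matrix(2.5, 3, 3))
  stk <- simulateFlimStack(gt, instrumentPhase = 0.2)
  ref <- simulateFlimStack(fluoresceinTruth(3, 3), instrumentPhase = 0.2)
  m1 <- computeLifetimeMap(stk, ref)
  stkW <- simulateFlimStack(gt, instrumentPhase = 0.2 + 2 * pi)
  m2 <- computeLifetimeMap(stkW, ref)
  expect_equal(m1@tauPhi, m2@tauPhi, tolerance = 1e-9)
})

test_that("photon-noise bias stays below 1% at high counts", {
  gt <- flimGroundTruth(matrix(2.5, 40, 40), intensityMap = 1000)
  stk <- simulateFlimStack(gt, photonNoise = TRUE, seed = 3)
  ref <- simulateFlimStack(fluoresceinTruth(40, 40, intensity = 5000))
  map <- computeLifetimeMap(stk, ref)
  expect_lt(abs(mean(map@tauPhi[map@valid]) / 2.5 - 1), 0.01)
})

test_that("ROI summaries report exact means and omit empty ROIs", {
  tau <- matrix(2.5, 6, 6)
  tau[, 4:6] <- 3.1
  gt <- flimGroundTruth(tau, intensityMap = 1000)
  stk <- simulateFlimStack(gt)
  ref <- simulateFlimStack(fluoresceinTruth(6, 6))
  map <- computeLifetimeMap(stk, ref)
  left <- matrix(FALSE, 6, 6); left[, 1:3] <- TRUE
  rois <- list(spine = left, shaft = !left,
               empty = matrix(FALSE, 6, 6))
  expect_warning(s <- summarizeRois(map, rois), "empty")
  expect_equal(s$mean_tau_ns[s$roi == "spine"], 2.5, tolerance = 1e-3)
  expect_equal(s$mean_tau_ns[s$roi == "shaft"], 3.1, tolerance = 1e-3)
  expect_false("empty" %in% s$roi)
})
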