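test_that("frozen dynamics produce constant tracks", {
  fld <- openField(nFrames = 30)
  det <- simulateReceptorDetections(fld, uniformPreset(dFree = 0), 5, seed = 1)
  for (tr in split(det, det$true_track_id)) {
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }
})

test_that("free-diffusion step variance matches 2 D dt per axis", {
  ## 50 receptors x 200 frames ~ 10^4 steps, far from any boundary
  fld <- openField(nFrames = 200, size = 5000)
  det <- simulateReceptorDetections(fld, uniformPreset(dFree = 0.1), 50,
                                    seed = 42)
  steps <- unlist(lapply(split(det, det$true_track_id), function(tr) {
    c(diff(tr$x_um), diff(tr$y_um))
  }))
  expect_gt(length(steps), 1.5e4)
  expect_equal(stats::var(steps), 2 * 0.1 * 0.05, tolerance = 0.05)
})

test_that("identical seeds give identical detection tables", {
  fld <- defaultField(nFrames = 40L)
  a <- simulateReceptorDetections(fld, shisa6Preset(), 10, seed = 99)
  b <- simulateReceptorDetections(fld, shisa6Preset(), 10, seed = 99)
  expect_identical(a, b)
  c <- simulateReceptorDetections(fld, shisa6Preset(), 10, seed = 100)
  expect_false(identical(a, c))
})

test_that("long-run trapped fraction approaches k_in / (k_in + k_out)", {
  fld <- openField(nFrames = 800)
  pre <- uniformPreset(dFree = 0.05, dTrapped = 1e-3, kIn = 0.6, kOut = 0.9)
  det <- simulateReceptorDetections(fld, pre, 40, seed = 5)
  frac <- mean(det$true_state == "trapped")
  expect_equal(frac, 0.6 / 1.5, tolerance = 0.08)
})

test_that("reflecting boundaries keep true positions inside the field", {
  fld <- fieldConfig(width = 2, height = 2, nFrames = 300L)
  det <- simulateReceptorDetections(fld, uniformPreset(dFree = 0.5), 20,
                                    seed = 3)
  expect_true(all(det$x_um >= 0 & det$x_um <= 2))
  expect_true(all(det$y_um >= 0 & det$y_um <= 2))
})

test_that("blinking removes rows at the configured rate", {
  fld <- openField(nFrames = 400)
  pre <- uniformPreset(dFree = 0.01, pDetect = 0.7)
  det <- simulateReceptorDetections(fld, pre, 25, seed = 8)
  expect_equal(nrow(det) / (25 * 400), 0.7, tolerance = 0.05)
})

test_that("invalid inputs are rejected with a message", {
  fld <- defaultField(nFrames = 10L)
  expect_error(simulateReceptorDetections(fld, controlPreset(), 0),
               "nReceptors")
  expect_error(fieldConfig(width = -1), "positive")
  expect_error(fieldConfig(nFrames = 3L), "at least 5")
  expect_error(mobilityParams(dFree = 0.01, dTrapped = 0.02), "dTrapped")
  expect_error(mobilityParams(dFree = 0.01, pDetect = 0), "pDetect")
})
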