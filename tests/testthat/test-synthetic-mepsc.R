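test_that("waveform peaks at the drawn amplitude", {
  p <- mepscParams(eventRate = 1e-9, noiseSd = 1e-12, duration = 2)
  ## direct waveform check: normalized peak equals 1 within 0.1%
  tms <- seq(0, 50, by = 0.01)
  w <- mepscWaveform(tms, riseTau = 0.5, decayTau = 5)
  expect_equal(max(w), 1, tolerance = 1e-3)
  ## analytic peak location
  tPk <- 0.5 * 5 / (5 - 0.5) * log(5 / 0.5)
  expect_equal(tms[which.max(w)], tPk, tolerance = 0.01)
})

test_that("zero-rate limit with zero noise gives a flat trace", {
  p <- mepscParams(eventRate = 1e-9, noiseSd = 1e-12, duration = 5)
  sim <- simulateMepscTrace(p, seed = 2)
  expect_equal(nrow(sim$events), 0)
  expect_lt(max(abs(traceCurrent(sim$trace))), 1e-10)
})

test_that("event counts follow the Poisson mean across seeds", {
  p <- mepscParams(eventRate = 0.5, duration = 60)
  counts <- vapply(1:100, function(s) nrow(simulateMepscTrace(p, seed = s)$events),
                   numeric(1))
  ## mean of 100 Poisson(30) draws: 99% CI half-width ~ 2.58*sqrt(30/100)
  expect_equal(mean(counts), 30, tolerance = 1.45 / 30)
})

test_that("identical seeds give identical traces and events", {
  p <- mepscParams(duration = 10)
  a <- simulateMepscTrace(p, seed = 11)
  b <- simulateMepscTrace(p, seed = 11)
  expect_identical(traceCurrent(a$trace), traceCurrent(b$trace))
  expect_identical(a$events, b$events)
})

test_that("parameter validity is enforced", {
  expect_error(mepscParams(riseTau = 3, decayTau = 2), "riseTau")
  expect_error(mepscParams(eventRate = -1), "positive")
})
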