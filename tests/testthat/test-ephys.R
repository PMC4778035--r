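dtFine <- 1e-5

## idealized single-event traces on a fine grid
rampTrace <- function(rampMs = 1) {
  tt <- seq(0, 0.02, by = dtFine)
  i <- -pmin(pmax((tt - 0.005) / (rampMs / 1000), 0), 1)
  currentTrace(i, dt = dtFine)
}
saturatingTrace <- function(tauMs = 1) {
  tt <- seq(0, 0.03, by = dtFine)
  i <- -(1 - exp(-pmax(tt - 0.005, 0) / (tauMs / 1000)))
  currentTrace(i, dt = dtFine)
}
decayTrace <- function(tauMs = 5) {
  tt <- seq(0, 0.08, by = dtFine)
  i <- -ifelse(tt < 0.005, 0, exp(-(tt - 0.005) / (tauMs / 1000)))
  currentTrace(i, dt = dtFine)
}

test_that("rise time matches closed forms on ramp, exponential and step", {
  ## linear ramp of duration 1 ms: (0.8 - 0.2) * 1 ms
  expect_equal(riseTime2080(rampTrace(1), c(0.004, 0.007)), 0.6,
               tolerance = 1e-3)
  ## saturating exponential, tau = 1 ms: ln(0.8/0.2) ~ 1.386 ms
  expect_equal(riseTime2080(saturatingTrace(1), c(0.004, 0.030)), log(4),
               tolerance = 1e-3)
  ## ideal step: bounded by one sample interval
  tt <- seq(0, 0.02, by = dtFine)
  step <- currentTrace(ifelse(tt < 0.01, 0, -1), dt = dtFine)
  expect_lt(riseTime2080(step, c(0.005, 0.015)), dtFine * 1000)
})

test_that("decay time matches closed forms on exponential and step", {
  ## mono-exponential: tau * ln 9
  expect_equal(decayTime9010(decayTrace(5), c(0.004, 0.08)), 5 * log(9),
               tolerance = 1e-3)
  expect_equal(decayTime9010(decayTrace(2), c(0.004, 0.08)), 2 * log(9),
               tolerance = 1e-3)
  ## step back to baseline: bounded by one sample
  tt <- seq(0, 0.02, by = dtFine)
  step <- currentTrace(ifelse(tt >= 0.005 & tt < 0.01, -1, 0), dt = dtFine)
  expect_lt(decayTime9010(step, c(0.004, 0.02)), dtFine * 1000)
})

test_that("exponential fitting recovers generating parameters", {
  ## single exponential self-fit within 0.5%
  fit <- fitExponentialDecay(decayTrace(5), c(0.005, 0.08), nComponents = 1)
  expect_true(fit$converged)
  expect_equal(fit$tau_weighted, 5, tolerance = 5e-3)
  ## two-component mixture recovered within 2% on noiseless input
  tt <- seq(0, 0.15, by = dtFine)
  y <- ifelse(tt < 0.005, 0,
              -(0.7 * exp(-(tt - 0.005) / 0.002) +
                0.3 * exp(-(tt - 0.005) / 0.020)))
  tr <- currentTrace(y, dt = dtFine)
  fit2 <- fitExponentialDecay(tr, c(0.005, 0.15), nComponents = 2)
  expect_true(fit2$converged)
  expect_equal(fit2$taus, c(2, 20), tolerance = 0.02)
  expect_equal(fit2$weights[1], 0.7, tolerance = 0.02)
  ## the auto rule prefers the double fit here
  fitA <- fitExponentialDecay(tr, c(0.005, 0.15))
  expect_equal(fitA$n_components, 2L)
})

test_that("steady-state fraction handles limiting cases", {
  tt <- seq(0, 1.2, by = 1e-4)
  flat <- currentTrace(ifelse(tt < 0.05, 0, -1), dt = 1e-4)
  expect_equal(steadyStateFraction(flat, c(0.05, 1.05)), 100,
               tolerance = 1e-6)
  full <- currentTrace(ifelse(tt >= 0.05 & tt < 0.06, -1, 0), dt = 1e-4)
  expect_equal(steadyStateFraction(full, c(0.05, 1.05)), 0,
               tolerance = 1e-6)
  expect_error(steadyStateFraction(flat, c(0.05, 0.10)), "shorter")
})

test_that("recovery fit recovers generating parameters within 1%", {
  ivs <- c(20, 50, 100, 200, 300, 400, 500, 750, 1000, 3000)
  ratios <- 1 - (1 - 0.1) * exp(-ivs / 100)
  traces <- Map(makePairTrace, ivs, ratios)
  rec <- recoveryAnalysis(traces, ivs)
  expect_equal(rec$tau_recovery, 100, tolerance = 0.01)
  expect_equal(rec$recovery_floor, 0.1, tolerance = 0.01)
})

test_that("degenerate and under-determined recovery inputs are refused", {
  ivs <- c(20, 100, 500, 1000)
  flat <- Map(makePairTrace, ivs, rep(1, 4))
  expect_warning(rec <- recoveryAnalysis(flat, ivs), "unidentifiable")
  expect_true(rec$degenerate)
  expect_true(is.na(rec$tau_recovery))
  few <- Map(makePairTrace, c(20, 100, 500), c(0.4, 0.7, 0.9))
  expect_warning(rec2 <- recoveryAnalysis(few, c(20, 100, 500)), "refused")
  expect_true(is.na(rec2$tau_recovery))
  expect_equal(rec2$ratio, c(0.4, 0.7, 0.9), tolerance = 1e-6)
})

test_that("train ratios measure non-interacting pulses exactly", {
  dt <- 1e-4
  tt <- seq(0, 1.2, by = dt)
  stim <- 0.1 + (0:9) * 0.1
  i <- rep(0, length(tt))
  for (s in stim) i <- i - 10 * pmax(0, 1 - abs(tt - (s + 0.002)) / 0.002)
  tr <- currentTrace(i, dt = dt)
  out <- trainRatios(tr, stim)
  expect_equal(out$normalized_amplitude, rep(1, 10), tolerance = 1e-6)
  ## second pulse at half amplitude
  tt2 <- seq(0, 0.3, by = dt)
  i2 <- -10 * pmax(0, 1 - abs(tt2 - 0.102) / 0.002) -
    5 * pmax(0, 1 - abs(tt2 - 0.202) / 0.002)
  out2 <- trainRatios(currentTrace(i2, dt = dt), c(0.1, 0.2))
  expect_equal(out2$normalized_amplitude, c(1, 0.5), tolerance = 1e-6)
})

test_that("reported features are invariant to amplitude scaling", {
  tr <- simulateGatingResponse(controlScheme(), pulseProtocol(1000, tailMs = 100),
                               dt = 1e-4)
  scaled <- currentTrace(traceCurrent(tr) * 3.7, dt = tr@dt,
                         metadata = tr@metadata)
  f1 <- extractFeatures(tr, c(0.010, 1.010))
  f2 <- extractFeatures(scaled, c(0.010, 1.010))
  for (nm in c("rise_20_80", "decay_90_10", "tau_des", "steady_state_pct"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6)
  expect_equal(f2$peak_amplitude, 3.7 * f1$peak_amplitude, tolerance = 1e-6)
})

test_that("mEPSC detector finds noiseless events at their onsets", {
  p <- mepscParams(eventRate = 0.5, noiseSd = 1e-6, duration = 20)
  sim <- simulateMepscTrace(p, seed = 41)
  det <- detectMepscs(sim$trace)
  expect_equal(det$summary$n, nrow(sim$events))
  matched <- vapply(sim$events$onset_s, function(o)
    any(abs(det$events$onset_s - o) < 0.002), logical(1))
  expect_true(all(matched))
})

test_that("sub-threshold traces yield zero events", {
  p <- mepscParams(amplitudeMean = 0.5, amplitudeCv = 0.01, noiseSd = 2,
                   duration = 20)
  sim <- simulateMepscTrace(p, seed = 42)
  det <- detectMepscs(sim$trace, thresholdSd = 6)
  expect_equal(det$summary$n, 0)
  expect_error(detectMepscs(currentTrace(rep(1, 1e5), dt = 1e-4)),
               "constant")
})

test_that("detector sensitivity and false positives meet the fixture spec", {
  p <- mepscParams(eventRate = 0.5, amplitudeMean = 16, amplitudeCv = 0.25,
                   noiseSd = 2, duration = 120)
  sim <- simulateMepscTrace(p, seed = 43)
  det <- detectMepscs(sim$trace)
  hits <- vapply(sim$events$onset_s, function(o)
    any(abs(det$events$onset_s - o) < 0.003), logical(1))
  expect_gte(mean(hits), 0.9)
  falseP <- vapply(det$events$onset_s, function(o)
    !any(abs(sim$events$onset_s - o) < 0.003), logical(1))
  expect_lte(sum(falseP) / 120, 0.05)
})
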