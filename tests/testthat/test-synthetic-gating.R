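test_that("zero agonist gives identically zero current", {
  proto <- glutamateProtocol(c(0.05, 0.05), c(0, 0), "blank")
  tr <- simulateGatingResponse(controlScheme(), proto, dt = 1e-4)
  expect_true(all(traceCurrent(tr) == 0))
})

test_that("occupancies stay conserved within 1e-6 at every sample", {
  for (scheme in list(controlScheme(), shisa6Scheme())) {
    tr <- simulateGatingResponse(scheme, pulseProtocol(1000, tailMs = 100),
                                 dt = 1e-4)
    occ <- tr@metadata$occupancy
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-6)
    expect_true(all(occ >= -1e-9 & occ <= 1 + 1e-9))
  }
})

test_that("two-state relaxation matches the closed-form exponential", {
  ## C <-> O with binding-proportional opening; D present but unreachable,
  ## draining to C so the zero-agonist stationary state stays unique
  k1 <- 500; k2 <- 300
  states <- c("C", "O", "D")
  k0 <- kc <- matrix(0, 3, 3, dimnames = list(states, states))
  kc["C", "O"] <- k1
  k0["O", "C"] <- k2
  k0["D", "C"] <- 50
  sc <- kineticScheme(states, c("closed", "open", "desensitized"),
                      conductance = c(0, 1, 0), rateConst = k0, rateConc = kc)
  proto <- glutamateProtocol(c(0.002, 0.05), c(0, 1), "step")
  tr <- simulateGatingResponse(sc, proto, dt = 1e-4)
  occ <- tr@metadata$occupancy
  tt <- traceTimes(tr)
  after <- tt >= 0.002
  tRel <- tt[after] - 0.002
  expected <- k1 / (k1 + k2) * (1 - exp(-(k1 + k2) * tRel))
  expect_lt(max(abs(occ[after, "O"] - expected)), 1e-4)
})

test_that("schemes without a unique resting state are rejected", {
  states <- c("C", "O", "D")
  k0 <- kc <- matrix(0, 3, 3, dimnames = list(states, states))
  kc["C", "O"] <- 100      # at zero agonist D is disconnected: no unique rest
  k0["O", "C"] <- 100
  sc <- kineticScheme(states, c("closed", "open", "desensitized"),
                      conductance = c(0, 1, 0), rateConst = k0, rateConc = kc)
  expect_error(simulateGatingResponse(sc, pulseProtocol(1), dt = 1e-4),
               "stationary")
})

test_that("dt must resolve the shortest protocol segment", {
  expect_error(simulateGatingResponse(controlScheme(), pulseProtocol(1),
                                      dt = 2e-4),
               "one tenth")
})

test_that("scheme validity enforces state classes and sign constraints", {
  expect_error(ampaScheme(-1, 1, 1, 1, 1, 1, 1), "rates")
  states <- c("C", "O")
  m <- matrix(0, 2, 2, dimnames = list(states, states))
  expect_error(kineticScheme(states, c("closed", "open"), c(0, 1), m, m),
               "desensitized")
})

test_that("scheme calibration is a fixed point at its own features and rejects infeasible targets", {
  base <- ampaScheme(kOn = 1e4, kOff = 2000, beta = 3000, alpha = 800,
                     kDesCG = 150, kDesO = 150, kRec = 16)
  f <- suppressWarnings(schemeFeatures(base))
  out <- suppressWarnings(
    calibrateScheme(base, f[c("decay_90_10", "steady_state_pct")]))
  expect_equal(attr(out, "residuals"),
               setNames(c(0, 0), c("decay_90_10", "steady_state_pct")))
  expect_equal(out@rateConst, base@rateConst)
  expect_error(calibrateScheme(base, c(steady_state_pct = 150)), "\\[0, 100\\]")
  expect_error(calibrateScheme(base, c(bogus_feature = 1)), "unknown")
})
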