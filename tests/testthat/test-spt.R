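test_that("well-separated particles are linked without identity errors", {
  ## two particles 10 um apart taking tiny steps
  det <- data.frame(
    frame = rep(0:9, each = 2),
    x_um = rep(c(1, 11), 10) + stats::rnorm(20, 0, 0.01),
    y_um = 5, true_track_id = rep(1:2, 10)
  )
  det <- det[order(det$frame), ]
  linked <- linkDetections(det, maxDisp = 0.5, maxGap = 0)
  expect_equal(length(unique(linked$track_id)), 2)
  tab <- table(linked$track_id, linked$true_track_id)
  expect_true(all(apply(tab > 0, 1, sum) == 1))   # one identity per track
})

test_that("gap closing bridges a single missed frame", {
  det <- data.frame(frame = c(0:3, 5:9), x_um = (c(0:3, 5:9)) * 0.05,
                    y_um = 1)
  linked <- linkDetections(det, maxDisp = 0.3, maxGap = 1)
  expect_equal(length(unique(linked$track_id)), 1)
  linkedNoGap <- linkDetections(det, maxDisp = 0.3, maxGap = 0)
  expect_equal(length(unique(linkedNoGap$track_id)), 2)
})

test_that("linking at moderate density recovers simulator identities", {
  fld <- fieldConfig(width = 20, height = 20, nFrames = 60L)
  pre <- uniformPreset(dFree = 0.05, sigma = 0.02, pDetect = 1)
  det <- simulateReceptorDetections(fld, pre, 50, seed = 13)
  linked <- linkDetections(det, maxDisp = 0.5, maxGap = 2)
  ## a link is correct when consecutive points in a track share the truth id
  correct <- total <- 0
  for (tr in split(linked, linked$track_id)) {
    if (nrow(tr) < 2L) next
    same <- tr$true_track_id[-1] == tr$true_track_id[-nrow(tr)]
    correct <- correct + sum(same); total <- total + length(same)
  }
  expect_gt(correct / total, 0.95)
})

test_that("unsorted detection tables are rejected and empty ones pass through", {
  det <- data.frame(frame = c(3, 1, 2), x_um = 1:3, y_um = 1:3)
  expect_error(linkDetections(det, maxDisp = 1), "sorted")
  empty <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0))
  expect_equal(nrow(linkDetections(empty, maxDisp = 1)), 0)
})

test_that("MSD matches the brute-force oracle on short trajectories", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    traj <- data.frame(frame = sort(sample(0:(n + 3), n)),
                       x_um = stats::rnorm(n), y_um = stats::rnorm(n))
    got <- computeMsd(traj, maxLag = 5, frameInterval = 0.05)
    want <- bruteForceMsd(traj, 5, 0.05)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("MSD closed forms: stationary and ballistic motion", {
  stat <- data.frame(frame = 0:9, x_um = 2, y_um = 3)
  msd <- computeMsd(stat, maxLag = 4, frameInterval = 0.05)
  expect_true(all(msd$msd == 0))
  s <- 0.2
  ball <- data.frame(frame = 0:9, x_um = (0:9) * s, y_um = 0)
  msd <- computeMsd(ball, maxLag = 4, frameInterval = 0.05)
  expect_equal(msd$msd, (1:4)^2 * s^2, tolerance = 1e-12)
})

test_that("D estimation is exact on a perfect line and clamps negatives", {
  msd <- data.frame(lag = 1:4, time_s = (1:4) * 0.05,
                    msd = 4 * 0.05 * (1:4) * 0.05, n_pairs = 10)
  expect_equal(as.numeric(estimateDiffusionCoefficient(msd)), 0.05)
  msd0 <- transform(msd, msd = 0)
  expect_equal(as.numeric(estimateDiffusionCoefficient(msd0)), 0)
  msdNeg <- transform(msd, msd = rev(msd))
  D <- estimateDiffusionCoefficient(msdNeg)
  expect_equal(as.numeric(D), 0)
  expect_true(attr(D, "clamped"))
  expect_error(estimateDiffusionCoefficient(msd[1:3, ]), "lags 1..4")
})

test_that("D estimate equals the brute-force OLS oracle on random tracks", {
  set.seed(11)
  for (rep in 1:5) {
    traj <- data.frame(frame = 0:9,
                       x_um = cumsum(stats::rnorm(10, 0, 0.1)),
                       y_um = cumsum(stats::rnorm(10, 0, 0.1)))
    msd <- computeMsd(traj, maxLag = 4, frameInterval = 0.05)
    expect_equal(as.numeric(estimateDiffusionCoefficient(msd)),
                 bruteForceD(bruteForceMsd(traj, 4, 0.05), 0.05),
                 tolerance = 1e-10)
  }
})

test_that("five in-cluster frames make a trajectory synaptic, four do not", {
  msk <- clusterMask(cbind(5, 5), radius = 0.5, width = 10, height = 10)
  inside <- data.frame(frame = 0:9, x_um = c(rep(5, 5), rep(8, 5)), y_um = 5)
  expect_equal(classifyCompartment(inside, msk), "synaptic")
  four <- data.frame(frame = 0:9, x_um = c(rep(5, 4), rep(8, 6)), y_um = 5)
  expect_equal(classifyCompartment(four, msk), "extrasynaptic")
  outside <- data.frame(frame = 0:9, x_um = 1, y_um = 1)
  expect_equal(classifyCompartment(outside, msk), "extrasynaptic")
  expect_error(classifyCompartment(inside, NULL), "mask")
})

test_that("compartment call equals a direct count of in-cluster frames", {
  msk <- clusterMask(rbind(c(3, 3), c(7, 7)), radius = 0.4,
                     width = 10, height = 10)
  set.seed(23)
  for (rep in 1:20) {
    traj <- data.frame(frame = 0:29, x_um = stats::runif(30, 0, 10),
                       y_um = stats::runif(30, 0, 10))
    nIn <- sum(sqrt((traj$x_um - 3)^2 + (traj$y_um - 3)^2) <= 0.4 |
               sqrt((traj$x_um - 7)^2 + (traj$y_um - 7)^2) <= 0.4)
    expect_equal(classifyCompartment(traj, msk),
                 if (nIn >= 5) "synaptic" else "extrasynaptic")
  }
})

test_that("mobility threshold is strict", {
  expect_equal(classifyMobility(0), "immobile")
  expect_equal(classifyMobility(0.005), "mobile")
  expect_equal(classifyMobility(0.00499), "immobile")
  expect_error(classifyMobility(0.1, threshold = 0), "threshold")
})

test_that("mobility summaries compute medians, fractions and histograms", {
  rec <- data.frame(track_id = 1:7,
                    D = c(0.01, 0.02, 0.03, 0.001, 0.002, 0.05, 0.04),
                    compartment = c(rep("synaptic", 3), rep("extrasynaptic", 4)),
                    mobility = c("mobile", "mobile", "mobile", "immobile",
                                 "immobile", "mobile", "mobile"),
                    condition = "x", cell = c(1, 1, 1, 1, 2, 2, 2))
  s <- summarizeMobility(rec)
  syn <- s$diffusion[s$diffusion$compartment == "synaptic", ]
  expect_equal(syn$median_D, 0.02)
  ## per-cell fractions 1/4 and 1/3, averaged
  expect_equal(s$immobile$mean_pct, 100 * mean(c(0.25, 1 / 3)))
  expect_equal(sum(s$histogram$x$mass), 1)
  ## single cell: SEM reported absent
  one <- summarizeMobility(rec[rec$cell == 1, ])
  expect_true(is.na(one$immobile$sem_pct))
  expect_equal(one$immobile$mean_pct, 25)
})

test_that("localization noise shifts the MSD intercept, not the slope", {
  fld <- openField(nFrames = 150, size = 5000)
  d <- 0.05
  noiseless <- simulateReceptorDetections(fld, uniformPreset(dFree = d),
                                          80, seed = 31)
  noisy <- simulateReceptorDetections(fld, uniformPreset(dFree = d,
                                                         sigma = 0.05),
                                      80, seed = 31)
  slopeOf <- function(det) {
    ds <- vapply(split(det, det$true_track_id), function(tr) {
      msd <- computeMsd(tr, maxLag = 4, frameInterval = 0.05)
      as.numeric(estimateDiffusionCoefficient(msd))
    }, numeric(1))
    stats::median(ds)
  }
  interceptOf <- function(det) {
    ints <- vapply(split(det, det$true_track_id), function(tr) {
      msd <- computeMsd(tr, maxLag = 4, frameInterval = 0.05)
      stats::coef(stats::lm(msd ~ time_s, msd))[1]
    }, numeric(1))
    stats::median(ints)
  }
  expect_equal(slopeOf(noisy), slopeOf(noiseless), tolerance = 0.10)
  ## intercept gains ~ 4 sigma^2
  expect_equal(interceptOf(noisy) - interceptOf(noiseless), 4 * 0.05^2,
               tolerance = 0.35)
})

test_that("immobile fraction increases with the trapping rate", {
  fld <- openField(nFrames = 150, size = 200)
  fracs <- vapply(c(0.005, 0.05, 0.4), function(kin) {
    pre <- uniformPreset(dFree = 0.05, dTrapped = 5e-4, kIn = kin,
                         kOut = 0.05, sigma = 0.02)
    det <- simulateReceptorDetections(fld, pre, 60, seed = 17)
    ds <- vapply(split(det, det$true_track_id), function(tr) {
      if (nrow(tr) < 8) return(NA_real_)
      msd <- computeMsd(tr, maxLag = 4, frameInterval = 0.05)
      if (!all(1:4 %in% msd$lag)) return(NA_real_)
      as.numeric(estimateDiffusionCoefficient(msd))
    }, numeric(1))
    mean(ds < 0.005, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})
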