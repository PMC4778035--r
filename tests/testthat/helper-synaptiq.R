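## Shared helpers: independent brute-force oracles and small builders.

## Exhaustive double-loop MSD oracle (independent of computeMsd).
bruteForceMsd <- function(traj, maxLag, frameInterval) {
  fr <- traj$frame; x <- traj$x_um; y <- traj$y_um
  out <- NULL
  for (n in seq_len(maxLag)) {
    sq <- c()
    for (i in seq_along(fr)) for (j in seq_along(fr)) {
      if (fr[j] - fr[i] == n)
        sq <- c(sq, (x[j] - x[i])^2 + (y[j] - y[i])^2)
    }
    if (length(sq))
      out <- rbind(out, data.frame(lag = n, time_s = n * frameInterval,
                                   msd = mean(sq), n_pairs = length(sq)))
  }
  out
}

## OLS D oracle on the first four lags (independent implementation).
bruteForceD <- function(msd, frameInterval) {
  sel <- msd[msd$lag <= 4, ]
  tt <- sel$lag * frameInterval
  fit <- stats::lm(sel$msd ~ tt)
  max(unname(stats::coef(fit)[2]) / 4, 0)
}

## Preset with uniform parameters for both compartments.
uniformPreset <- function(dFree, dTrapped = 0, kIn = 0, kOut = 1,
                          sigma = 0, pDetect = 1, name = "test") {
  mp <- mobilityParams(dFree = dFree, dTrapped = dTrapped, kTrapIn = kIn,
                       kTrapOut = kOut, localizationSigma = sigma,
                       pDetect = pDetect)
  conditionPreset(name, synaptic = mp, extrasynaptic = mp, pSynaptic = 0)
}

## Open field (no clusters) of the given size.
openField <- function(nFrames, size = 1000) {
  fieldConfig(width = size, height = size, nFrames = nFrames)
}

## Synthetic paired-pulse trace with unit first peak and given second-peak
## ratio: two short triangular deflections with onsets in the metadata.
makePairTrace <- function(intervalMs, ratio, dt = 1e-4) {
  onset1 <- 0.010
  onset2 <- onset1 + 0.001 + intervalMs / 1000
  tEnd <- onset2 + 0.020
  tt <- seq(0, tEnd, by = dt)
  bump <- function(t0, amp) {
    tri <- pmax(0, 1 - abs(tt - (t0 + 0.002)) / 0.002)
    -amp * tri
  }
  i <- bump(onset1, 1) + bump(onset2, ratio)
  currentTrace(i, dt = dt,
               metadata = list(pulseOnsets = c(onset1, onset2)))
}
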