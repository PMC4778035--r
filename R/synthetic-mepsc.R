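#' Normalized difference-of-exponentials synaptic waveform
#'
#' `w(t) = (exp(-t/decayTau) - exp(-t/riseTau)) / peak`, normalized so the
#' maximum equals 1. Times and time constants in ms.
#'
#' @param t times in ms (>= 0).
#' @param riseTau,decayTau time constants in ms, `riseTau < decayTau`.
#' @return waveform values (unit peak).
#' @export
mepscWaveform <- function(t, riseTau, decayTau) {
  tPeak <- riseTau * decayTau / (decayTau - riseTau) * log(decayTau / riseTau)
  peak <- exp(-tPeak / decayTau) - exp(-tPeak / riseTau)
  (exp(-t / decayTau) - exp(-t / riseTau)) / peak
}

#' Simulate a miniature-EPSC voltage-clamp trace
#'
#' Event onsets follow a Poisson process at `eventRate`; each event adds a
#' difference-of-exponentials waveform normalized to a peak amplitude drawn
#' from a normal distribution truncated at zero (negative-going, i.e. inward
#' current). Gaussian recording noise is added throughout. Identical seeds
#' give identical traces.
#'
#' @param params a [MepscParams-class].
#' @param seed integer seed.
#' @return list with `trace` (a [CurrentTrace-class]) and `events`
#'   (data.frame `onset_s`, `amplitude_pA` of the ground-truth events).
#' @examples
#' sim <- simulateMepscTrace(mepscParams(duration = 10), seed = 7)
#' nrow(sim$events)
#' @export
simulateMepscTrace <- function(params, seed = 1L) {
  stopifnot(is(params, "MepscParams"))
  validObject(params)
  withSeed(seed, {
    fs <- params@samplingRate
    nS <- round(params@duration * fs)
    nEv <- stats::rpois(1, params@eventRate * params@duration)
    onsets <- sort(stats::runif(nEv, 0, params@duration))
    ## truncated-normal amplitudes (pA, positive magnitudes)
    sdA <- params@amplitudeCv * params@amplitudeMean
    u <- stats::runif(nEv, stats::pnorm(0, params@amplitudeMean, sdA), 1)
    amps <- stats::qnorm(u, params@amplitudeMean, sdA)

    i <- stats::rnorm(nS, 0, params@noiseSd)
    ## waveform template sampled on the trace grid, truncated at 1e-4 of peak
    tEndMs <- params@decayTau * log(1e4)
    nW <- max(2L, ceiling(tEndMs / 1000 * fs))
    wf <- mepscWaveform((seq_len(nW) - 1L) / fs * 1000,
                        params@riseTau, params@decayTau)
    for (k in seq_len(nEv)) {
      s0 <- floor(onsets[k] * fs) + 1L
      sEnd <- min(nS, s0 + nW - 1L)
      len <- sEnd - s0 + 1L
      if (len > 0L)
        i[s0:sEnd] <- i[s0:sEnd] - amps[k] * wf[seq_len(len)]
    }
    list(
      trace = currentTrace(i, dt = 1 / fs,
                           metadata = list(kind = "mepsc", seed = seed,
                                           eventRate = params@eventRate)),
      events = data.frame(onset_s = onsets, amplitude_pA = amps)
    )
  })
}
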