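#' Detect miniature EPSCs in a voltage-clamp trace
#'
#' Events are detected as negative-going excursions of the smoothed,
#' baseline-subtracted trace beyond `thresholdSd` robust noise standard
#' deviations (median absolute deviation). Crossings closer than
#' `refractoryMs` are merged, and candidates whose 20-80% rise is slower
#' than `maxRiseMs` (slow drifts rather than synaptic events) are rejected.
#' Per-event features are measured with [riseTime2080()] and
#' [decayTime9010()] on the raw trace around each onset.
#'
#' @param trace a [CurrentTrace-class] of at least 10 s for frequency
#'   estimates.
#' @param thresholdSd detection threshold in noise SDs (default 5).
#' @param refractoryMs minimum separation between event onsets (ms).
#' @param smoothMs moving-average window used for detection (ms).
#' @param featureSmoothMs moving-average window of the measurement filter:
#'   per-event rise, decay and amplitude are read from the trace low-pass
#'   filtered at this scale (ms), which suppresses the systematic shortening
#'   of threshold-crossing intervals by recording noise.
#' @param maxRiseMs rise-time ceiling for accepting an event (ms).
#' @return list with `events` (data.frame `onset_s`, `amplitude_pA`,
#'   `rise_20_80_ms`, `decay_90_10_ms`) and `summary` (list `n`,
#'   `frequency_hz`, `mean_amplitude_pA`, `mean_rise_ms`, `mean_decay_ms`,
#'   `threshold_pA`, `noise_sd_pA`).
#' @examples
#' sim <- simulateMepscTrace(mepscParams(duration = 20), seed = 3)
#' det <- detectMepscs(sim$trace)
#' det$summary$n
#' @export
detectMepscs <- function(trace, thresholdSd = 5, refractoryMs = 5,
                         smoothMs = 0.3, featureSmoothMs = 0.8,
                         maxRiseMs = 5) {
  stopifnot(is(trace, "CurrentTrace"))
  fs <- 1 / trace@dt
  i <- trace@i
  nS <- length(i)
  if (nS * trace@dt < 10) warning("trace shorter than 10 s; frequency estimate unreliable")

  ## smooth, estimate baseline and robust noise SD
  wl <- max(1L, round(smoothMs / 1000 * fs))
  sm <- movingAverage(i, wl)
  baseline <- stats::median(sm)
  noiseSd <- stats::mad(sm)
  if (noiseSd <= 0 && max(abs(sm - baseline)) == 0)
    stop("noise estimate is zero (constant trace)")
  ## noise-free recordings with sparse events: any excursion is an event
  thr <- thresholdSd * noiseSd
  onsetSd <- max(noiseSd, 1e-12)

  below <- (baseline - sm) > thr          # negative-going excursions
  starts <- which(below & !c(FALSE, below[-nS]))
  if (length(starts) == 0L) {
    return(list(events = data.frame(onset_s = numeric(0),
                                    amplitude_pA = numeric(0),
                                    rise_20_80_ms = numeric(0),
                                    decay_90_10_ms = numeric(0)),
                summary = list(n = 0L, frequency_hz = 0,
                               mean_amplitude_pA = NA_real_,
                               mean_rise_ms = NA_real_,
                               mean_decay_ms = NA_real_,
                               threshold_pA = thr, noise_sd_pA = noiseSd)))
  }
  ## refractory merging of threshold crossings
  keep <- c(TRUE, diff(starts) > refractoryMs / 1000 * fs)
  starts <- starts[keep]

  tt <- traceTimes(trace)
  ## measurement filter: features read from the low-pass-filtered trace
  wf <- max(1L, round(featureSmoothMs / 1000 * fs))
  iF <- movingAverage(i, wf)
  traceF <- currentTrace(iF, dt = trace@dt, t0 = trace@t0)
  events <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    ## onset: walk back to where the excursion drops below 1 noise SD
    back <- s
    while (back > 1L && (baseline - sm[back - 1L]) > onsetSd) back <- back - 1L
    onset <- tt[back]
    winEnd <- min(tt[nS], onset + 0.040)
    if (k < length(starts)) winEnd <- min(winEnd, tt[starts[k + 1L]] - trace@dt)
    ## work on a small slice around the event
    i0 <- max(1L, back - round(0.005 * fs))
    i1 <- min(nS, round(winEnd / trace@dt) + 1L)
    seg <- currentTrace(iF[i0:i1], dt = trace@dt, t0 = tt[i0])
    evWin <- c(onset, winEnd)
    ## local baseline from the 3 ms before onset
    pre <- tt[i0:i1] >= onset - 0.003 & tt[i0:i1] < onset - 0.0005
    base <- if (any(pre)) stats::median(iF[i0:i1][pre]) else baseline
    win <- tt[i0:i1] >= onset
    ampl <- base - min(iF[i0:i1][win])
    rise <- suppressWarnings(riseTime2080(seg, evWin, baseline = base))
    dec <- suppressWarnings(decayTime9010(seg, evWin, baseline = base))
    c(onset = onset, amplitude = ampl, rise = rise, decay = dec)
  })
  ev <- do.call(rbind, events)
  ok <- is.finite(ev[, "rise"]) & ev[, "rise"] <= maxRiseMs &
        ev[, "amplitude"] > 0
  ev <- ev[ok, , drop = FALSE]

  dur <- nS * trace@dt
  events <- data.frame(onset_s = ev[, "onset"], amplitude_pA = ev[, "amplitude"],
                       rise_20_80_ms = ev[, "rise"],
                       decay_90_10_ms = ev[, "decay"])
  list(events = events,
       summary = list(n = nrow(events), frequency_hz = nrow(events) / dur,
                      mean_amplitude_pA = mean(events$amplitude_pA),
                      mean_rise_ms = mean(events$rise_20_80_ms, na.rm = TRUE),
                      mean_decay_ms = mean(events$decay_90_10_ms, na.rm = TRUE),
                      threshold_pA = thr, noise_sd_pA = noiseSd))
}

## Centred moving average with edge truncation.
movingAverage <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  ## fill the edges with the original samples
  na <- is.na(y)
  y[na] <- x[na]
  y
}
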