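## Recovery-from-desensitization and pulse-train analysis.

#' Recovery from desensitization across paired-pulse intervals
#'
#' For each trace (one paired 1-ms application per inter-pulse interval) the
#' two peak amplitudes are measured relative to their local pre-pulse
#' baselines and the ratio peak2/peak1 is formed. The ratios are then fitted
#' with the saturating exponential `R(dt) = 1 - (1 - R0) * exp(-dt/tau)`,
#' yielding the recovery time constant `tau_recovery` and the floor `R0`.
#'
#' @param traces list of [CurrentTrace-class] objects from
#'   [pairedPulseProtocol()] simulations (or recordings with two pulses whose
#'   onsets are given in `metadata$pulseOnsets`).
#' @param intervalsMs inter-pulse intervals in ms, one per trace.
#' @param peakWindowMs window after each pulse onset within which the peak is
#'   measured (default 8 ms).
#' @return list with `intervals_ms`, `ratio`, `tau_recovery` (ms),
#'   `recovery_floor` and `degenerate` (TRUE when the ratios carry no
#'   recovery signal and the fit is not identifiable). With fewer than 4
#'   intervals the fit is refused (`tau_recovery = NA`) and ratios are still
#'   returned.
#' @examples
#' ivs <- c(20, 50, 100, 200, 300, 400, 500, 750, 1000, 3000)
#' trs <- lapply(ivs, function(k)
#'   simulateGatingResponse(controlScheme(), pairedPulseProtocol(k), dt = 1e-4))
#' recoveryAnalysis(trs, ivs)$tau_recovery
#' @export
recoveryAnalysis <- function(traces, intervalsMs, peakWindowMs = 8) {
  stopifnot(length(traces) == length(intervalsMs))
  ord <- order(intervalsMs)
  traces <- traces[ord]; intervalsMs <- intervalsMs[ord]

  ratio <- vapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    onsets <- tr@metadata$pulseOnsets
    if (is.null(onsets) || length(onsets) != 2L)
      stop("each trace must carry two pulse onsets in metadata$pulseOnsets")
    a1 <- pulsePeakAmplitude(tr, onsets[1], peakWindowMs)
    a2 <- pulsePeakAmplitude(tr, onsets[2], peakWindowMs)
    a2 / a1
  }, numeric(1))

  out <- list(intervals_ms = intervalsMs, ratio = ratio,
              tau_recovery = NA_real_, recovery_floor = NA_real_,
              degenerate = FALSE)
  if (length(intervalsMs) < 4L) {
    warning("fewer than 4 intervals: recovery fit refused")
    return(out)
  }
  if (stats::sd(ratio) < 1e-4 || all(ratio > 0.995)) {
    warning("ratios carry no recovery signal; tau unidentifiable")
    out$degenerate <- TRUE
    return(out)
  }
  dtm <- intervalsMs
  fit <- fitWithFallback(
    ratio ~ 1 - (1 - R0) * exp(-dtm / tau),
    data = list(dtm = dtm, ratio = ratio),
    start = list(R0 = max(min(ratio), 0), tau = stats::median(dtm)),
    lower = c(R0 = 0, tau = 1e-3), upper = c(R0 = 1, tau = Inf),
    check = function(cf) cf["tau"] > 0 && cf["R0"] >= -1e-6 && cf["R0"] <= 1)
  if (is.null(fit)) {
    warning("recovery fit did not converge")
    return(out)
  }
  cf <- stats::coef(fit)
  out$tau_recovery <- unname(cf["tau"])
  out$recovery_floor <- unname(cf["R0"])
  out
}

## Peak deflection after one pulse onset, relative to the local pre-pulse
## baseline (median of the 1 ms preceding the onset).
pulsePeakAmplitude <- function(trace, onset, peakWindowMs = 8) {
  tt <- traceTimes(trace)
  pre <- tt >= onset - 0.001 & tt < onset
  if (!any(pre)) pre <- seq_len(max(2L, round(0.001 / trace@dt)))
  base <- stats::median(trace@i[pre])
  win <- tt >= onset & tt <= onset + peakWindowMs / 1000
  d <- trace@i[win] - base
  max(abs(d))
}

#' Normalized response amplitudes over a stimulus train
#'
#' Measures the peak of each pulse response relative to its local pre-pulse
#' baseline. When responses overlap (high-frequency trains), the decaying
#' tail of the previous response is removed by fitting a single exponential
#' to the last part of the preceding inter-pulse segment and subtracting its
#' extrapolation. Amplitudes are normalized to the first pulse.
#'
#' @param trace a [CurrentTrace-class].
#' @param stimTimes pulse onset times in seconds (>= 2, regularly or
#'   irregularly spaced, pulses separated by at least 3 samples).
#' @param peakWindowMs window after each onset in which the peak is sought;
#'   defaults to the smaller of 8 ms and 90% of the shortest inter-pulse
#'   interval.
#' @return data.frame with `pulse` (1..n), `amplitude` (pA) and
#'   `normalized_amplitude` (pulse 1 = 1); pulses where the tail
#'   extrapolation failed are flagged in the `flagged` column.
#' @export
trainRatios <- function(trace, stimTimes, peakWindowMs = NULL) {
  stimTimes <- sort(stimTimes)
  n <- length(stimTimes)
  if (n < 2L) stop("a train needs at least two pulses")
  tt <- traceTimes(trace)
  isi <- min(diff(stimTimes))
  if (isi < 3 * trace@dt) stop("pulses must be separated by at least 3 samples")
  if (is.null(peakWindowMs)) peakWindowMs <- min(8, 0.9 * isi * 1000)

  ## global baseline and polarity from the pre-train segment
  pre <- tt < stimTimes[1]
  base0 <- if (any(pre)) stats::median(trace@i[pre]) else trace@i[1]
  d <- traceDeflection(trace, baseline = base0)

  amp <- numeric(n); flagged <- logical(n)
  for (k in seq_len(n)) {
    win <- which(tt >= stimTimes[k] & tt <= stimTimes[k] + peakWindowMs / 1000)
    if (k == 1L) {
      amp[k] <- max(d$y[win])
      next
    }
    ## model the residual tail of the previous response
    tail0 <- stimTimes[k - 1L] + 0.4 * (stimTimes[k] - stimTimes[k - 1L])
    seg <- which(tt >= tail0 & tt < stimTimes[k])
    tailFit <- NULL
    if (length(seg) >= 5L && max(d$y[seg]) > 0) {
      ts <- tt[seg] - tt[seg[1]]
      ys <- d$y[seg]
      tailFit <- fitWithFallback(
        ys ~ A * exp(-ts / tau),
        data = list(ts = ts, ys = ys),
        start = list(A = max(ys[1], 1e-9),
                     tau = max(diff(range(ts)) / 2, 1e-6)),
        lower = c(A = 0, tau = 1e-9),
        check = function(cf) cf["A"] >= 0 && cf["tau"] > 0)
    }
    if (!is.null(tailFit)) {
      cf <- stats::coef(tailFit)
      extrap <- cf["A"] * exp(-(tt[win] - tt[seg[1]]) / cf["tau"])
      amp[k] <- max(d$y[win] - extrap)
    } else {
      ## fall back to the pre-pulse level and flag the pulse
      prePulse <- which(tt >= stimTimes[k] - 0.001 & tt < stimTimes[k])
      lvl <- if (length(prePulse)) stats::median(d$y[prePulse]) else 0
      amp[k] <- max(d$y[win]) - lvl
      flagged[k] <- TRUE
    }
  }
  data.frame(pulse = seq_len(n), amplitude = d$polarity * amp,
             normalized_amplitude = amp / amp[1], flagged = flagged)
}
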