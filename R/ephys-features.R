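## Current-trace feature extraction: 20-80% rise time, 90-10% decay time,
## exponential desensitization fits and steady-state fraction. All features
## operate on the baseline-subtracted deflection and are polarity-agnostic
## (inward currents are negative by convention).

## Levenberg-Marquardt fit that tries box bounds first and falls back to the
## unconstrained fit (validated by `check`) when the bounded solver fails.
fitWithFallback <- function(formula, data, start, lower = NULL, upper = NULL,
                            check = function(cf) TRUE) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      upper = upper, control = ctrl),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = start, control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit) && !isTRUE(check(stats::coef(fit)))) fit <- NULL
  }
  fit
}

## Baseline-subtracted deflection (positive at the response peak) and the
## polarity used. Baseline defaults to the median of `baselineWindow` (s).
traceDeflection <- function(trace, baselineWindow = NULL, baseline = NULL) {
  tt <- traceTimes(trace)
  if (is.null(baseline)) {
    if (is.null(baselineWindow)) {
      nb <- max(2L, min(length(trace@i), round(0.010 / trace@dt)))
      baseline <- stats::median(trace@i[seq_len(nb)])
    } else {
      sel <- tt >= baselineWindow[1] & tt < baselineWindow[2]
      if (!any(sel)) stop("baseline window contains no samples")
      baseline <- stats::median(trace@i[sel])
    }
  }
  d <- trace@i - baseline
  polarity <- if (max(d) >= -min(d)) 1 else -1
  list(y = polarity * d, baseline = baseline, polarity = polarity)
}

## Linearly interpolated time at which `y` first crosses `level` moving
## forward (direction = "up" while rising, "down" while decaying) within
## index range idx. Returns NA when there is no crossing.
crossingTime <- function(tt, y, level, idx, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(idx) < 2L) return(NA_real_)
  yy <- y[idx]
  hit <- if (direction == "up") which(yy[-1] >= level & yy[-length(yy)] < level)
         else which(yy[-1] <= level & yy[-length(yy)] > level)
  if (length(hit) == 0L) {
    ## already past the level at the first sample
    if ((direction == "up" && yy[1] >= level) ||
        (direction == "down" && yy[1] <= level)) return(tt[idx[1]])
    return(NA_real_)
  }
  k <- hit[1L]
  i0 <- idx[k]; i1 <- idx[k + 1L]
  frac <- (level - y[i0]) / (y[i1] - y[i0])
  tt[i0] + frac * (tt[i1] - tt[i0])
}

#' 20-80% rise time of an evoked response
#'
#' The time taken by the baseline-subtracted current to climb from 20% to
#' 80% of the maximal amplitude, with linear interpolation between the
#' samples bracketing each crossing.
#'
#' @param trace a [CurrentTrace-class].
#' @param eventWindow numeric `c(start, end)` in seconds containing a single
#'   monotonic-onset event; default is the full trace.
#' @param baseline baseline current (pA); estimated from the 10 ms preceding
#'   the window when `NULL`.
#' @return rise time in ms, or `NA` (with a warning) when no crossing exists.
#' @examples
#' tr <- simulateGatingResponse(controlScheme(), pulseProtocol(1), dt = 5e-5)
#' riseTime2080(tr)
#' @export
riseTime2080 <- function(trace, eventWindow = NULL, baseline = NULL) {
  tt <- traceTimes(trace)
  if (is.null(eventWindow)) eventWindow <- range(tt)
  if (is.null(baseline)) {
    pre <- tt >= eventWindow[1] - 0.010 & tt < eventWindow[1]
    baseline <- if (any(pre)) stats::median(trace@i[pre]) else NULL
  }
  d <- traceDeflection(trace, baseline = baseline)
  idx <- which(tt >= eventWindow[1] & tt <= eventWindow[2])
  if (length(idx) < 2L) stop("event window contains fewer than two samples")
  pk <- idx[which.max(d$y[idx])]
  peak <- d$y[pk]
  if (peak <= 0) { warning("no event deflection in window"); return(NA_real_) }
  rising <- idx[idx <= pk]
  t20 <- crossingTime(tt, d$y, 0.2 * peak, rising, "up")
  t80 <- crossingTime(tt, d$y, 0.8 * peak, rising, "up")
  if (is.na(t20) || is.na(t80)) {
    warning("rise-time crossings not found"); return(NA_real_)
  }
  (t80 - t20) * 1000
}

#' 90-10% decay time of an evoked response
#'
#' Interpolated time between the 90% and 10% crossings of the
#' baseline-subtracted peak, measured after the peak.
#'
#' @param trace a [CurrentTrace-class].
#' @param eventWindow `c(start, end)` s; the peak is located inside it and
#'   crossings are searched from the peak to the end of the trace.
#' @param baseline baseline current (pA); estimated before the window when
#'   `NULL`.
#' @return decay time in ms, or `NA` (with a warning) when the trace never
#'   relaxes to 10%.
#' @export
decayTime9010 <- function(trace, eventWindow = NULL, baseline = NULL) {
  tt <- traceTimes(trace)
  if (is.null(eventWindow)) eventWindow <- range(tt)
  if (is.null(baseline)) {
    pre <- tt >= eventWindow[1] - 0.010 & tt < eventWindow[1]
    baseline <- if (any(pre)) stats::median(trace@i[pre]) else NULL
  }
  d <- traceDeflection(trace, baseline = baseline)
  idx <- which(tt >= eventWindow[1] & tt <= eventWindow[2])
  if (length(idx) < 2L) stop("event window contains fewer than two samples")
  pk <- idx[which.max(d$y[idx])]
  peak <- d$y[pk]
  if (peak <= 0) { warning("no event deflection in window"); return(NA_real_) }
  falling <- pk:length(tt)
  t90 <- crossingTime(tt, d$y, 0.9 * peak, falling, "down")
  t10 <- crossingTime(tt, d$y, 0.1 * peak, falling, "down")
  if (is.na(t90) || is.na(t10)) {
    warning("decay did not reach the 10% level"); return(NA_real_)
  }
  (t10 - t90) * 1000
}

#' Exponential fit to a current decay
#'
#' Nonlinear least squares of
#' `A * (w * exp(-t/tau1) + (1 - w) * exp(-t/tau2)) + C`
#' (single component when `nComponents = 1`) to the baseline-subtracted
#' deflection over `window`. The initializer is fixed and documented (time
#' constants from the 90-10% decay time, `w = 0.5`), so fits are
#' deterministic. With `nComponents = "auto"` both models are fitted and the
#' double-exponential is reported only when it improves the residual norm by
#' more than 5%.
#'
#' @param trace a [CurrentTrace-class].
#' @param window `c(start, end)` in seconds; should begin at the post-peak
#'   sample and contain at least 20 samples.
#' @param nComponents 1, 2 or `"auto"`.
#' @param baseline baseline current (pA), estimated pre-window when `NULL`.
#' @return list with `taus` (ms), `weights` (amplitude fractions summing to
#'   1), `tau_weighted` (amplitude-weighted mean, ms), `residual_norm`,
#'   `converged`, `n_components`.
#' @export
fitExponentialDecay <- function(trace, window = NULL, nComponents = "auto",
                                baseline = NULL) {
  tt <- traceTimes(trace)
  if (is.null(window)) window <- range(tt)
  d <- traceDeflection(trace, baseline = baseline)
  idx <- which(tt >= window[1] & tt <= window[2])
  if (length(idx) < 20L) stop("decay window must contain at least 20 samples")
  t <- tt[idx] - tt[idx[1]]
  y <- d$y[idx]

  ## deterministic initializer: tau from the 90-10% time, w = 0.5
  tau0 <- decayTime9010(trace, eventWindow = window, baseline = baseline)
  tau0 <- if (is.na(tau0) || tau0 <= 0) max(t) * 1000 / 3 else tau0 / log(9)
  tau0 <- tau0 / 1000                       # seconds
  C0 <- mean(y[t >= max(t) * 0.95])
  A0 <- max(y[1] - C0, .Machine$double.eps)

  fit1 <- fitWithFallback(
    y ~ A * exp(-t / tau) + C,
    data = list(t = t, y = y),
    start = list(A = A0, tau = tau0, C = C0),
    lower = c(A = 0, tau = 1e-7, C = -Inf),
    check = function(cf) cf["tau"] > 0)
  fit2 <- if (!identical(nComponents, 1)) fitWithFallback(
    y ~ A * (w * exp(-t / tau1) + (1 - w) * exp(-t / tau2)) + C,
    data = list(t = t, y = y),
    start = list(A = A0, w = 0.5, tau1 = tau0 / 3, tau2 = tau0 * 3, C = C0),
    lower = c(A = 0, w = 0, tau1 = 1e-7, tau2 = 1e-7, C = -Inf),
    upper = c(A = Inf, w = 1, tau1 = Inf, tau2 = Inf, C = Inf),
    check = function(cf) cf["tau1"] > 0 && cf["tau2"] > 0 &&
      cf["w"] >= -1e-6 && cf["w"] <= 1 + 1e-6) else NULL

  rnorm1 <- if (is.null(fit1)) Inf else sqrt(sum(stats::residuals(fit1)^2))
  rnorm2 <- if (is.null(fit2)) Inf else sqrt(sum(stats::residuals(fit2)^2))

  useDouble <- switch(as.character(nComponents),
    "1" = FALSE,
    "2" = TRUE,
    "auto" = is.finite(rnorm2) && rnorm2 < 0.95 * rnorm1,
    stop("'nComponents' must be 1, 2 or \"auto\"")
  )
  if (useDouble && is.null(fit2)) useDouble <- FALSE
  if (!useDouble && is.null(fit1) && !is.null(fit2)) useDouble <- TRUE
  if ((useDouble && is.null(fit2)) || (!useDouble && is.null(fit1))) {
    warning("exponential fit did not converge")
    return(list(taus = NA_real_, weights = NA_real_, tau_weighted = NA_real_,
                residual_norm = NA_real_, converged = FALSE,
                n_components = NA_integer_))
  }

  if (useDouble) {
    cf <- stats::coef(fit2)
    taus <- sort(c(cf["tau1"], cf["tau2"])) * 1000
    w <- unname(if (cf["tau1"] <= cf["tau2"]) cf["w"] else 1 - cf["w"])
    weights <- c(w, 1 - w)
    list(taus = unname(taus), weights = weights,
         tau_weighted = unname(sum(taus * weights)),
         residual_norm = rnorm2, converged = TRUE, n_components = 2L)
  } else {
    cf <- stats::coef(fit1)
    list(taus = unname(cf["tau"]) * 1000, weights = 1,
         tau_weighted = unname(cf["tau"]) * 1000,
         residual_norm = rnorm1, converged = TRUE, n_components = 1L)
  }
}

#' Steady-state current as a percentage of the peak
#'
#' Mean baseline-subtracted current over the final 100 ms of a sustained
#' agonist application, divided by the peak deflection, times 100.
#'
#' @param trace a [CurrentTrace-class].
#' @param applicationWindow `c(onset, offset)` of the application in s; the
#'   application must last at least 100 ms.
#' @param baseline baseline current (pA), estimated pre-onset when `NULL`.
#' @param ssWindowMs width of the steady-state window (ms, default 100).
#' @return percentage of peak (0-100).
#' @export
steadyStateFraction <- function(trace, applicationWindow, baseline = NULL,
                                ssWindowMs = 100) {
  if (diff(applicationWindow) < ssWindowMs / 1000)
    stop("application shorter than the steady-state window")
  tt <- traceTimes(trace)
  if (is.null(baseline)) {
    pre <- tt >= applicationWindow[1] - 0.010 & tt < applicationWindow[1]
    baseline <- if (any(pre)) stats::median(trace@i[pre]) else NULL
  }
  d <- traceDeflection(trace, baseline = baseline)
  idx <- which(tt >= applicationWindow[1] & tt <= applicationWindow[2])
  peak <- max(d$y[idx])
  if (peak <= 0) stop("no deflection during the application")
  ss <- tt >= applicationWindow[2] - ssWindowMs / 1000 &
        tt <= applicationWindow[2]
  100 * mean(d$y[ss]) / peak
}

#' Full feature set of an evoked current
#'
#' Convenience wrapper combining [riseTime2080()], [decayTime9010()],
#' [fitExponentialDecay()] and [steadyStateFraction()] for one agonist
#' application. The desensitization fit and steady-state fraction are
#' computed only when the application lasts at least 200 ms.
#'
#' @param trace a [CurrentTrace-class].
#' @param applicationWindow `c(onset, offset)` of the agonist application (s).
#' @param nComponents passed to [fitExponentialDecay()].
#' @return list with `rise_20_80`, `decay_90_10` (ms), `peak_amplitude`
#'   (pA, signed), and for sustained applications `tau_des` (ms),
#'   `tau_components`, `tau_weights`, `steady_state_pct`.
#' @export
extractFeatures <- function(trace, applicationWindow, nComponents = "auto") {
  tt <- traceTimes(trace)
  pre <- tt >= applicationWindow[1] - 0.010 & tt < applicationWindow[1]
  baseline <- if (any(pre)) stats::median(trace@i[pre]) else trace@i[1]
  d <- traceDeflection(trace, baseline = baseline)
  idx <- which(tt >= applicationWindow[1])
  pk <- idx[which.max(d$y[idx])]
  out <- list(
    rise_20_80 = riseTime2080(trace, c(applicationWindow[1], tt[pk]),
                              baseline = baseline),
    decay_90_10 = decayTime9010(trace, c(applicationWindow[1], max(tt)),
                                baseline = baseline),
    peak_amplitude = d$polarity * d$y[pk]
  )
  if (diff(applicationWindow) >= 0.2) {
    fit <- fitExponentialDecay(trace, c(tt[pk], applicationWindow[2]),
                               nComponents = nComponents, baseline = baseline)
    out$tau_des <- fit$tau_weighted
    out$tau_components <- fit$taus
    out$tau_weights <- fit$weights
    out$steady_state_pct <- steadyStateFraction(trace, applicationWindow,
                                                baseline = baseline)
  }
  out
}
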