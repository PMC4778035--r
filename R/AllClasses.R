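#' @import methods
NULL

## ---------------------------------------------------------------------------
## Imaging field and receptor-mobility parameters
## ---------------------------------------------------------------------------

#' Imaging field geometry for receptor-tracking simulations
#'
#' Describes the region of membrane in which receptors are simulated: field
#' extent, pixel size, the disc-shaped postsynaptic clusters (Homer1C-style
#' labels) and the acquisition timing (frame interval, number of frames).
#'
#' @slot width,height field extent in micrometres.
#' @slot pixelSize micrometres per camera pixel (metadata only; detections are
#'   emitted in micrometres).
#' @slot clusterCenters two-column matrix of cluster centres (um).
#' @slot clusterRadius cluster disc radius (um).
#' @slot frameInterval acquisition interval in seconds (default 0.050).
#' @slot nFrames number of consecutive frames.
#' @export
setClass("FieldConfig",
  representation(
    width = "numeric", height = "numeric", pixelSize = "numeric",
    clusterCenters = "matrix", clusterRadius = "numeric",
    frameInterval = "numeric", nFrames = "integer"
  )
)

setValidity("FieldConfig", function(object) {
  msg <- character()
  for (s in c("width", "height", "pixelSize", "clusterRadius", "frameInterval"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  if (object@nFrames < 5L)
    msg <- c(msg, "'nFrames' must be at least 5")
  cc <- object@clusterCenters
  if (ncol(cc) != 2L)
    msg <- c(msg, "'clusterCenters' must have two columns (x, y)")
  else if (nrow(cc) > 0L && length(msg) == 0L) {
    r <- object@clusterRadius
    inside <- cc[, 1] >= r & cc[, 1] <= object@width - r &
              cc[, 2] >= r & cc[, 2] <= object@height - r
    if (!all(inside))
      msg <- c(msg, "all clusters must lie inside the field")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FieldConfig
#'
#' @param width,height field extent in micrometres.
#' @param pixelSize micrometres per pixel.
#' @param clusterCenters two-column matrix (or data.frame) of cluster centre
#'   coordinates in micrometres.
#' @param clusterRadius disc radius of each synaptic cluster (um).
#' @param frameInterval frame interval in seconds.
#' @param nFrames number of frames acquired.
#' @return a [FieldConfig-class] object.
#' @examples
#' fieldConfig(clusterCenters = cbind(c(5, 10), c(5, 10)))
#' @export
fieldConfig <- function(width = 40, height = 40, pixelSize = 0.16,
                        clusterCenters = matrix(numeric(0), ncol = 2),
                        clusterRadius = 0.3,
                        frameInterval = 0.050, nFrames = 200L) {
  cc <- as.matrix(clusterCenters)
  if (length(cc) == 0L) cc <- matrix(numeric(0), ncol = 2)
  new("FieldConfig", width = width, height = height, pixelSize = pixelSize,
      clusterCenters = cc, clusterRadius = clusterRadius,
      frameInterval = frameInterval, nFrames = as.integer(nFrames))
}

#' Two-state mobility parameters for one membrane compartment
#'
#' Receptors alternate between a freely diffusing state and a trapped
#' (scaffold-bound) state. Diffusion is Brownian with coefficient `dFree`
#' or `dTrapped`; switching is a two-state Markov chain with rates
#' `kTrapIn` (free -> trapped) and `kTrapOut` (trapped -> free).
#'
#' @slot dFree,dTrapped diffusion coefficients (um^2/s), `dTrapped <= dFree`.
#' @slot kTrapIn,kTrapOut state-switching rates (1/s).
#' @slot localizationSigma isotropic localization error SD (um).
#' @slot pDetect per-frame detection probability (blinking).
#' @export
setClass("MobilityParams",
  representation(
    dFree = "numeric", dTrapped = "numeric",
    kTrapIn = "numeric", kTrapOut = "numeric",
    localizationSigma = "numeric", pDetect = "numeric"
  )
)

setValidity("MobilityParams", function(object) {
  msg <- character()
  vals <- c(dFree = object@dFree, dTrapped = object@dTrapped,
            kTrapIn = object@kTrapIn, kTrapOut = object@kTrapOut,
            localizationSigma = object@localizationSigma)
  if (any(!is.finite(vals)) || any(vals < 0))
    msg <- c(msg, "rates, diffusion coefficients and localization sigma must be finite and >= 0")
  if (object@dTrapped > object@dFree)
    msg <- c(msg, "'dTrapped' must not exceed 'dFree'")
  if (!is.finite(object@pDetect) || object@pDetect <= 0 || object@pDetect > 1)
    msg <- c(msg, "'pDetect' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct MobilityParams
#'
#' @param dFree,dTrapped diffusion coefficients in um^2/s.
#' @param kTrapIn,kTrapOut trapping/untrapping rates in 1/s.
#' @param localizationSigma localization error SD in um.
#' @param pDetect per-frame detection probability.
#' @return a [MobilityParams-class] object.
#' @export
mobilityParams <- function(dFree, dTrapped = 5e-4, kTrapIn = 0, kTrapOut = 1,
                           localizationSigma = 0.02, pDetect = 0.95) {
  new("MobilityParams", dFree = dFree, dTrapped = dTrapped,
      kTrapIn = kTrapIn, kTrapOut = kTrapOut,
      localizationSigma = localizationSigma, pDetect = pDetect)
}

#' Experimental condition preset for receptor-mobility simulations
#'
#' Bundles the synaptic and extrasynaptic mobility parameter sets under a
#' condition label (e.g. control, auxiliary-subunit overexpression, or the
#' PDZ-ligand deletion mutant).
#'
#' @slot name condition label.
#' @slot synaptic,extrasynaptic [MobilityParams-class] used while a receptor
#'   is inside / outside a synaptic cluster.
#' @slot pSynaptic fraction of receptors initially placed inside clusters.
#' @export
setClass("ConditionPreset",
  representation(name = "character", synaptic = "MobilityParams",
                 extrasynaptic = "MobilityParams", pSynaptic = "numeric")
)

setValidity("ConditionPreset", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (object@pSynaptic < 0 || object@pSynaptic > 1)
    msg <- c(msg, "'pSynaptic' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a ConditionPreset
#'
#' @param name condition label.
#' @param synaptic,extrasynaptic [MobilityParams-class] objects.
#' @param pSynaptic fraction of receptors seeded inside clusters.
#' @return a [ConditionPreset-class] object.
#' @export
conditionPreset <- function(name, synaptic, extrasynaptic, pSynaptic = 0.3) {
  new("ConditionPreset", name = name, synaptic = synaptic,
      extrasynaptic = extrasynaptic, pSynaptic = pSynaptic)
}

## ---------------------------------------------------------------------------
## Gating scheme and glutamate protocols
## ---------------------------------------------------------------------------

#' Markov gating scheme for a ligand-gated channel
#'
#' Transition rates are affine in the agonist concentration:
#' `rate(i -> j, c) = rateConst[i, j] + c * rateConc[i, j]` with `c` in mM.
#' The generator matrix Q(c) has these off-diagonal entries and rows summing
#' to zero. Macroscopic current is proportional to the conductance-weighted
#' occupancy of the open state(s).
#'
#' @slot stateNames state labels.
#' @slot stateClass one of `"closed"`, `"open"`, `"desensitized"` per state.
#' @slot conductance per-state conductance weight (> 0 only for open states).
#' @slot rateConst constant part of each transition rate (1/s).
#' @slot rateConc concentration-proportional part (1/s per mM).
#' @export
setClass("KineticScheme",
  representation(stateNames = "character", stateClass = "character",
                 conductance = "numeric", rateConst = "matrix",
                 rateConc = "matrix")
)

setValidity("KineticScheme", function(object) {
  msg <- character()
  n <- length(object@stateNames)
  if (length(object@stateClass) != n || length(object@conductance) != n)
    msg <- c(msg, "stateClass and conductance must match stateNames in length")
  if (!all(object@stateClass %in% c("closed", "open", "desensitized")))
    msg <- c(msg, "stateClass entries must be closed/open/desensitized")
  for (cl in c("closed", "open", "desensitized"))
    if (!cl %in% object@stateClass)
      msg <- c(msg, sprintf("scheme needs at least one %s state", cl))
  if (!all(dim(object@rateConst) == c(n, n)) ||
      !all(dim(object@rateConc) == c(n, n)))
    msg <- c(msg, "rate matrices must be n x n")
  else {
    off <- row(object@rateConst) != col(object@rateConst)
    if (any(object@rateConst[off] < 0) || any(object@rateConc[off] < 0))
      msg <- c(msg, "all transition rates must be >= 0")
  }
  if (length(msg) == 0L) {
    open <- object@stateClass == "open"
    if (any(object@conductance[!open] != 0) || any(object@conductance[open] <= 0))
      msg <- c(msg, "conductance must be > 0 for open states and 0 otherwise")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a KineticScheme
#'
#' @param stateNames character vector of state labels.
#' @param stateClass `"closed"`, `"open"` or `"desensitized"` per state.
#' @param conductance conductance weights (positive for open states only).
#' @param rateConst matrix of constant transition rates (1/s); diagonal ignored.
#' @param rateConc matrix of concentration-proportional rates (1/s/mM).
#' @return a [KineticScheme-class] object.
#' @export
kineticScheme <- function(stateNames, stateClass, conductance,
                          rateConst, rateConc) {
  rateConst <- as.matrix(rateConst); rateConc <- as.matrix(rateConc)
  diag(rateConst) <- 0; diag(rateConc) <- 0
  dimnames(rateConst) <- dimnames(rateConc) <- list(stateNames, stateNames)
  new("KineticScheme", stateNames = stateNames, stateClass = stateClass,
      conductance = conductance, rateConst = rateConst, rateConc = rateConc)
}

#' Generator matrix of a scheme at a given agonist concentration
#'
#' @param scheme a [KineticScheme-class].
#' @param conc agonist concentration in mM.
#' @return the generator matrix Q with rows summing to zero.
#' @export
generatorMatrix <- function(scheme, conc) {
  Q <- scheme@rateConst + conc * scheme@rateConc
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Piecewise-constant glutamate application protocol
#'
#' @slot name protocol label.
#' @slot durations segment durations in seconds.
#' @slot concentrations agonist concentration per segment in mM.
#' @export
setClass("GlutamateProtocol",
  representation(name = "character", durations = "numeric",
                 concentrations = "numeric")
)

setValidity("GlutamateProtocol", function(object) {
  msg <- character()
  if (length(object@durations) != length(object@concentrations) ||
      length(object@durations) == 0L)
    msg <- c(msg, "durations and concentrations must be equal-length, non-empty")
  if (any(object@durations <= 0)) msg <- c(msg, "durations must be > 0")
  if (any(object@concentrations < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GlutamateProtocol
#'
#' @param durations segment durations (s).
#' @param concentrations segment concentrations (mM).
#' @param name protocol label.
#' @return a [GlutamateProtocol-class] object.
#' @export
glutamateProtocol <- function(durations, concentrations, name = "protocol") {
  new("GlutamateProtocol", name = name, durations = as.numeric(durations),
      concentrations = as.numeric(concentrations))
}

## ---------------------------------------------------------------------------
## Current traces and mEPSC parameters
## ---------------------------------------------------------------------------

#' Uniformly sampled whole-cell current trace
#'
#' @slot i current samples in pA (inward currents negative).
#' @slot dt sampling interval in seconds.
#' @slot t0 time of the first sample (s).
#' @slot metadata list of protocol/provenance metadata.
#' @export
setClass("CurrentTrace",
  representation(i = "numeric", dt = "numeric", t0 = "numeric",
                 metadata = "list")
)

setValidity("CurrentTrace", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive number")
  if (length(object@i) < 2L) msg <- c(msg, "trace needs at least two samples")
  if (any(!is.finite(object@i))) msg <- c(msg, "current samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a CurrentTrace
#'
#' @param i current samples (pA).
#' @param dt sampling interval (s).
#' @param t0 time of first sample (s).
#' @param metadata list of metadata carried with the trace.
#' @return a [CurrentTrace-class] object.
#' @export
currentTrace <- function(i, dt, t0 = 0, metadata = list()) {
  new("CurrentTrace", i = as.numeric(i), dt = dt, t0 = t0, metadata = metadata)
}

#' Sample times of a trace
#' @param trace a [CurrentTrace-class].
#' @return numeric vector of sample times in seconds.
#' @export
traceTimes <- function(trace) trace@t0 + (seq_along(trace@i) - 1L) * trace@dt

#' Current samples of a trace
#' @param trace a [CurrentTrace-class].
#' @return numeric vector of current samples (pA).
#' @export
traceCurrent <- function(trace) trace@i

#' Miniature-EPSC simulation parameters
#'
#' Events arrive as a Poisson process; each adds a difference-of-exponentials
#' waveform normalized to a peak amplitude drawn from a truncated normal.
#'
#' @slot eventRate mean event rate (Hz).
#' @slot amplitudeMean,amplitudeCv peak amplitude mean (pA) and CV.
#' @slot riseTau,decayTau waveform time constants (ms), `riseTau < decayTau`.
#' @slot noiseSd additive Gaussian noise SD (pA).
#' @slot duration trace duration (s).
#' @slot samplingRate sampling rate (Hz).
#' @export
setClass("MepscParams",
  representation(eventRate = "numeric", amplitudeMean = "numeric",
                 amplitudeCv = "numeric", riseTau = "numeric",
                 decayTau = "numeric", noiseSd = "numeric",
                 duration = "numeric", samplingRate = "numeric")
)

setValidity("MepscParams", function(object) {
  msg <- character()
  vals <- c(object@eventRate, object@amplitudeMean, object@amplitudeCv,
            object@riseTau, object@decayTau, object@noiseSd,
            object@duration, object@samplingRate)
  if (any(!is.finite(vals)) || any(vals[-6] <= 0) || object@noiseSd < 0)
    msg <- c(msg, "all parameters must be positive (noiseSd may be 0)")
  if (object@riseTau >= object@decayTau)
    msg <- c(msg, "'riseTau' must be smaller than 'decayTau'")
  if (length(msg)) msg else TRUE
})

#' Construct MepscParams
#'
#' @param eventRate event rate in Hz.
#' @param amplitudeMean,amplitudeCv amplitude distribution (pA, unitless CV).
#' @param riseTau,decayTau waveform time constants in ms.
#' @param noiseSd recording noise SD in pA.
#' @param duration trace duration in s.
#' @param samplingRate sampling rate in Hz.
#' @return a [MepscParams-class] object.
#' @export
mepscParams <- function(eventRate = 0.5, amplitudeMean = 16, amplitudeCv = 0.25,
                        riseTau = 0.55, decayTau = 2.4, noiseSd = 2,
                        duration = 60, samplingRate = 1e4) {
  new("MepscParams", eventRate = eventRate, amplitudeMean = amplitudeMean,
      amplitudeCv = amplitudeCv, riseTau = riseTau, decayTau = decayTau,
      noiseSd = noiseSd, duration = duration, samplingRate = samplingRate)
}

## ---------------------------------------------------------------------------
## FLIM containers
## ---------------------------------------------------------------------------

#' Ground truth for a frequency-domain FLIM acquisition
#'
#' @slot lifetimeMap matrix of per-pixel lifetimes (ns).
#' @slot intensityMap matrix of mean photon counts per pixel per phase frame.
#' @slot modFreq modulation frequency (Hz), default 40 MHz.
#' @slot nPhases number of phase steps, default 12.
#' @slot referenceLifetime lifetime assigned to the reference dye (ns).
#' @export
setClass("FlimGroundTruth",
  representation(lifetimeMap = "matrix", intensityMap = "matrix",
                 modFreq = "numeric", nPhases = "integer",
                 referenceLifetime = "numeric")
)

setValidity("FlimGroundTruth", function(object) {
  msg <- character()
  if (any(object@lifetimeMap < 0)) msg <- c(msg, "lifetimes must be >= 0")
  if (!all(dim(object@lifetimeMap) == dim(object@intensityMap)))
    msg <- c(msg, "lifetime and intensity maps must have identical shape")
  if (object@nPhases < 3L) msg <- c(msg, "'nPhases' must be >= 3")
  if (object@modFreq <= 0) msg <- c(msg, "'modFreq' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct FlimGroundTruth
#'
#' @param lifetimeMap matrix of lifetimes (ns).
#' @param intensityMap matrix of expected counts; a scalar is recycled.
#' @param modFreq modulation frequency (Hz).
#' @param nPhases number of phase steps.
#' @param referenceLifetime reference dye lifetime (ns).
#' @return a [FlimGroundTruth-class] object.
#' @export
flimGroundTruth <- function(lifetimeMap, intensityMap = 1000,
                            modFreq = 4e7, nPhases = 12L,
                            referenceLifetime = 4.00) {
  lifetimeMap <- as.matrix(lifetimeMap)
  if (length(intensityMap) == 1L)
    intensityMap <- matrix(intensityMap, nrow(lifetimeMap), ncol(lifetimeMap))
  new("FlimGroundTruth", lifetimeMap = lifetimeMap,
      intensityMap = as.matrix(intensityMap), modFreq = modFreq,
      nPhases = as.integer(nPhases), referenceLifetime = referenceLifetime)
}

#' Stack of phase-shifted intensity images
#'
#' Holds the `nPhases` homodyne intensity frames of one frequency-domain
#' acquisition, with the modulation metadata and (optionally) the measured
#' phase and modulation of the reference acquisition used for lifetime
#' referencing.
#'
#' @slot images array (rows x cols x nPhases) of intensities.
#' @slot modFreq modulation frequency (Hz).
#' @slot nPhases number of phase steps.
#' @slot referencePhase,referenceModulation measured phasor of the reference
#'   acquisition (`NA` until set).
#' @slot referenceLifetime lifetime assigned to the reference dye (ns).
#' @slot metadata provenance list.
#' @export
setClass("PhaseStack",
  representation(images = "array", modFreq = "numeric", nPhases = "integer",
                 referencePhase = "numeric", referenceModulation = "numeric",
                 referenceLifetime = "numeric", metadata = "list")
)

setValidity("PhaseStack", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 3L) msg <- c(msg, "'images' must be a 3-d array")
  else if (d[3] != object@nPhases)
    msg <- c(msg, "third array dimension must equal nPhases")
  if (object@nPhases < 3L) msg <- c(msg, "'nPhases' must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Construct a PhaseStack
#'
#' @param images array (rows x cols x nPhases).
#' @param modFreq modulation frequency (Hz).
#' @param referenceLifetime reference dye lifetime (ns).
#' @param referencePhase,referenceModulation measured reference phasor.
#' @param metadata provenance list.
#' @return a [PhaseStack-class] object.
#' @export
phaseStack <- function(images, modFreq = 4e7, referenceLifetime = 4.00,
                       referencePhase = NA_real_,
                       referenceModulation = NA_real_, metadata = list()) {
  new("PhaseStack", images = images, modFreq = modFreq,
      nPhases = dim(images)[3], referencePhase = referencePhase,
      referenceModulation = referenceModulation,
      referenceLifetime = referenceLifetime, metadata = metadata)
}

#' Per-pixel lifetime map
#'
#' @slot tauPhi matrix of phase lifetimes (ns).
#' @slot tauMod matrix of modulation lifetimes (ns, diagnostics).
#' @slot valid logical matrix of pixels passing the intensity floor.
#' @slot metadata provenance list.
#' @export
setClass("LifetimeMap",
  representation(tauPhi = "matrix", tauMod = "matrix", valid = "matrix",
                 metadata = "list")
)

setValidity("LifetimeMap", function(object) {
  ok <- object@valid & is.finite(object@tauPhi)
  if (any(object@tauPhi[ok] < 0))
    "phase lifetimes must be >= 0 on valid pixels" else TRUE
})

## ---------------------------------------------------------------------------
## Cluster mask
## ---------------------------------------------------------------------------

#' Synaptic cluster mask
#'
#' Disc-list representation of the postsynaptic clusters used to classify
#' trajectory compartments.
#'
#' @slot centers two-column matrix of disc centres (um).
#' @slot radius disc radius (um).
#' @slot width,height covered field extent (um).
#' @export
setClass("ClusterMask",
  representation(centers = "matrix", radius = "numeric",
                 width = "numeric", height = "numeric")
)

setValidity("ClusterMask", function(object) {
  msg <- character()
  if (ncol(object@centers) != 2L)
    msg <- c(msg, "'centers' must have two columns")
  if (object@radius <= 0) msg <- c(msg, "'radius' must be > 0")
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "field extent must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterMask
#'
#' @param centers two-column matrix of disc centres (um).
#' @param radius disc radius (um).
#' @param width,height covered field extent (um).
#' @return a [ClusterMask-class] object.
#' @export
clusterMask <- function(centers, radius, width, height) {
  centers <- as.matrix(centers)
  if (length(centers) == 0L) centers <- matrix(numeric(0), ncol = 2)
  new("ClusterMask", centers = centers, radius = radius,
      width = width, height = height)
}

#' Cluster mask implied by a FieldConfig
#' @param field a [FieldConfig-class].
#' @return the [ClusterMask-class] of its synaptic discs.
#' @export
fieldMask <- function(field) {
  clusterMask(field@clusterCenters, field@clusterRadius,
              field@width, field@height)
}

## ---------------------------------------------------------------------------
## show() methods
## ---------------------------------------------------------------------------

setMethod("show", "FieldConfig", function(object) {
  cat(sprintf("FieldConfig: %.1f x %.1f um, %d clusters (r = %.2f um), %d frames @ %.0f ms\n",
              object@width, object@height, nrow(object@clusterCenters),
              object@clusterRadius, object@nFrames,
              object@frameInterval * 1000))
})

setMethod("show", "MobilityParams", function(object) {
  cat(sprintf("MobilityParams: D_free %.4g, D_trapped %.4g um^2/s; k_in %.3g, k_out %.3g 1/s; sigma %.3g um; p_detect %.2f\n",
              object@dFree, object@dTrapped, object@kTrapIn, object@kTrapOut,
              object@localizationSigma, object@pDetect))
})

setMethod("show", "ConditionPreset", function(object) {
  cat(sprintf("ConditionPreset '%s' (p_synaptic = %.2f)\n  synaptic:      ",
              object@name, object@pSynaptic))
  show(object@synaptic)
  cat("  extrasynaptic: ")
  show(object@extrasynaptic)
})

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme: %s\n",
              paste(sprintf("%s(%s)", object@stateNames,
                            substr(object@stateClass, 1, 1)), collapse = " ")))
  nz <- which(object@rateConst > 0 | object@rateConc > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    i <- nz[k, 1]; j <- nz[k, 2]
    cat(sprintf("  %s -> %s: %.4g + %.4g*c 1/s\n", object@stateNames[i],
                object@stateNames[j], object@rateConst[i, j],
                object@rateConc[i, j]))
  }
})

setMethod("show", "GlutamateProtocol", function(object) {
  cat(sprintf("GlutamateProtocol '%s': %d segments, total %.4g s\n",
              object@name, length(object@durations), sum(object@durations)))
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %d samples @ %.3g s (%.4g s total), range [%.4g, %.4g] pA\n",
              length(object@i), object@dt, length(object@i) * object@dt,
              min(object@i), max(object@i)))
})

setMethod("show", "MepscParams", function(object) {
  cat(sprintf("MepscParams: %.2g Hz, %.3g pA (CV %.2f), rise/decay %.3g/%.3g ms, noise %.3g pA, %.3g s @ %.3g kHz\n",
              object@eventRate, object@amplitudeMean, object@amplitudeCv,
              object@riseTau, object@decayTau, object@noiseSd,
              object@duration, object@samplingRate / 1000))
})

setMethod("show", "PhaseStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("PhaseStack: %d x %d px, %d phases @ %.3g MHz (reference %.2f ns%s)\n",
              d[1], d[2], object@nPhases, object@modFreq / 1e6,
              object@referenceLifetime,
              if (is.na(object@referencePhase)) ", unreferenced" else ""))
})

setMethod("show", "LifetimeMap", function(object) {
  ok <- object@valid
  cat(sprintf("LifetimeMap: %d x %d px, %d valid; mean tau_phi %.3f ns\n",
              nrow(object@tauPhi), ncol(object@tauPhi), sum(ok),
              mean(object@tauPhi[ok])))
})

setMethod("show", "ClusterMask", function(object) {
  cat(sprintf("ClusterMask: %d discs (r = %.2f um) over %.1f x %.1f um\n",
              nrow(object@centers), object@radius, object@width,
              object@height))
})
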