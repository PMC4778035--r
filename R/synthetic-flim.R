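## Frequency-domain FLIM simulation: homodyne phase stacks from lifetime or
## phasor ground truth, optional Poisson photon noise, and FRET mixtures.

#' Phasor coordinates of a mono-exponential lifetime
#'
#' At angular modulation frequency `w = 2*pi*modFreq`, a lifetime `tau`
#' produces phase `phi = atan(w*tau)` and demodulation
#' `m = 1/sqrt(1 + (w*tau)^2)`.
#'
#' @param tau lifetime(s) in ns.
#' @param modFreq modulation frequency in Hz.
#' @return list with `phi` (rad), `m`, and the phasor coordinates `g`, `s`.
#' @export
lifetimePhasor <- function(tau, modFreq = 4e7) {
  wt <- 2 * pi * modFreq * tau * 1e-9
  list(phi = atan(wt), m = 1 / sqrt(1 + wt^2),
       g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Phasor of an intensity-weighted FRET mixture
#'
#' A pixel containing a fraction `fretFraction` of FRET-quenched donors (by
#' emitted intensity) and the rest unquenched donors has the phasor of the
#' intensity-weighted sum of the two mono-exponential components. The
#' apparent phase lifetime `tan(phi)/w` of such a mixture lies between the
#' two component lifetimes.
#'
#' @param donorTau unquenched donor lifetime (ns).
#' @param quenchedTau FRET-quenched donor lifetime (ns).
#' @param fretFraction intensity fraction of the quenched component, in
#'   `[0, 1]`.
#' @param modFreq modulation frequency (Hz).
#' @return list with `phi`, `m`, `g`, `s` and the apparent phase lifetime
#'   `tauPhi` (ns).
#' @export
fretMixturePhasor <- function(donorTau, quenchedTau, fretFraction,
                              modFreq = 4e7) {
  pd <- lifetimePhasor(donorTau, modFreq)
  pq <- lifetimePhasor(quenchedTau, modFreq)
  g <- (1 - fretFraction) * pd$g + fretFraction * pq$g
  s <- (1 - fretFraction) * pd$s + fretFraction * pq$s
  w <- 2 * pi * modFreq
  list(phi = atan2(s, g), m = sqrt(g^2 + s^2), g = g, s = s,
       tauPhi = (s / g) / w * 1e9)
}

#' Intensity fraction of quenched donors giving a target phase lifetime
#'
#' Solves for the FRET fraction at which the mixture's apparent phase
#' lifetime equals `targetTauPhi`. Used once to calibrate the packaged
#' FRET-condition fixtures.
#'
#' @param donorTau,quenchedTau component lifetimes (ns).
#' @param targetTauPhi desired apparent phase lifetime (ns), inside
#'   `(quenchedTau, donorTau)`.
#' @param modFreq modulation frequency (Hz).
#' @return the FRET fraction in `[0, 1]`.
#' @export
calibrateFretFraction <- function(donorTau, quenchedTau, targetTauPhi,
                                  modFreq = 4e7) {
  if (targetTauPhi >= donorTau || targetTauPhi <= quenchedTau)
    stop("target lifetime must lie between the component lifetimes")
  stats::uniroot(function(f)
    fretMixturePhasor(donorTau, quenchedTau, f, modFreq)$tauPhi - targetTauPhi,
    c(0, 1), tol = 1e-12)$root
}

#' Simulate a homodyne phase stack
#'
#' Generates the `nPhases` phase-stepped intensity frames of a
#' frequency-domain FLIM acquisition. A pixel with lifetime `tau` emits
#' `I * (1 + m * cos(2*pi*k/n - phi))` at phase step `k`, with
#' `phi = atan(w*tau)`, `m = 1/sqrt(1+(w*tau)^2)` and `w = 2*pi*modFreq`.
#' An instrumental phase shift and demodulation can be applied on top (all
#' acquisitions of one session share them; referencing removes them). With
#' `photonNoise = TRUE` every sample is replaced by a Poisson draw.
#'
#' @param truth a [FlimGroundTruth-class].
#' @param photonNoise add Poisson counting noise?
#' @param seed integer seed (used only when `photonNoise` is TRUE).
#' @param instrumentPhase instrumental phase offset (rad).
#' @param instrumentMod instrumental demodulation factor in (0, 1].
#' @return a [PhaseStack-class].
#' @examples
#' gt <- flimGroundTruth(matrix(2.5, 8, 8))
#' stk <- simulateFlimStack(gt)
#' @export
simulateFlimStack <- function(truth, photonNoise = FALSE, seed = 1L,
                              instrumentPhase = 0, instrumentMod = 1) {
  stopifnot(is(truth, "FlimGroundTruth"))
  validObject(truth)
  ph <- lifetimePhasor(truth@lifetimeMap, truth@modFreq)
  simulatePhasorStack(phi = ph$phi, m = ph$m,
                      intensity = truth@intensityMap,
                      modFreq = truth@modFreq, nPhases = truth@nPhases,
                      referenceLifetime = truth@referenceLifetime,
                      photonNoise = photonNoise, seed = seed,
                      instrumentPhase = instrumentPhase,
                      instrumentMod = instrumentMod)
}

#' @rdname simulateFlimStack
#' @param phi,m matrices of per-pixel emission phase (rad) and modulation
#'   depth; used when the ground truth is a phasor (e.g. FRET mixtures)
#'   rather than a single lifetime.
#' @param intensity matrix (or scalar) of mean counts per pixel per frame.
#' @param modFreq modulation frequency (Hz).
#' @param nPhases number of phase steps.
#' @param referenceLifetime reference dye lifetime carried in metadata (ns).
#' @export
simulatePhasorStack <- function(phi, m, intensity = 1000, modFreq = 4e7,
                                nPhases = 12L, referenceLifetime = 4.00,
                                photonNoise = FALSE, seed = 1L,
                                instrumentPhase = 0, instrumentMod = 1) {
  phi <- as.matrix(phi); m <- as.matrix(m)
  stopifnot(all(dim(phi) == dim(m)))
  if (length(intensity) == 1L)
    intensity <- matrix(intensity, nrow(phi), ncol(phi))
  nPhases <- as.integer(nPhases)
  imgs <- array(NA_real_, c(nrow(phi), ncol(phi), nPhases))
  for (k in seq_len(nPhases)) {
    theta <- 2 * pi * (k - 1L) / nPhases
    imgs[, , k] <- intensity *
      (1 + instrumentMod * m * cos(theta - phi - instrumentPhase))
  }
  if (photonNoise) {
    imgs <- withSeed(seed, {
      array(stats::rpois(length(imgs), pmax(imgs, 0)), dim(imgs))
    })
  }
  phaseStack(imgs, modFreq = modFreq, referenceLifetime = referenceLifetime,
             metadata = list(photonNoise = photonNoise,
                             instrumentPhase = instrumentPhase,
                             instrumentMod = instrumentMod,
                             seed = if (photonNoise) seed else NA_integer_))
}

#' Ground truth for a uniform fluorescein reference acquisition
#'
#' @param nrow,ncol image size in pixels.
#' @param intensity mean counts per pixel per frame.
#' @param lifetime reference lifetime in ns (fluorescein convention 4.00).
#' @param modFreq modulation frequency (Hz).
#' @param nPhases number of phase steps.
#' @return a [FlimGroundTruth-class] with a uniform lifetime map.
#' @export
fluoresceinTruth <- function(nrow = 32, ncol = 32, intensity = 5000,
                             lifetime = 4.00, modFreq = 4e7, nPhases = 12L) {
  flimGroundTruth(matrix(lifetime, nrow, ncol), intensityMap = intensity,
                  modFreq = modFreq, nPhases = nPhases,
                  referenceLifetime = lifetime)
}
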