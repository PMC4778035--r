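#' Simulate quantum-dot receptor detections under a two-state trapping model
#'
#' Receptors diffuse in a rectangular membrane field containing disc-shaped
#' postsynaptic clusters. Each receptor alternates between a freely diffusing
#' and a trapped state (two-state Markov chain); the switching rates and
#' diffusion coefficients are taken from the synaptic or extrasynaptic
#' parameter set of `preset` according to the receptor's current position.
#' Reported positions carry isotropic Gaussian localization error, and each
#' receptor is detected per frame with probability `pDetect` (quantum-dot
#' blinking). Field boundaries are reflecting.
#'
#' Per-axis true displacement variance is `2 * D * frameInterval` with `D`
#' the coefficient of the current state, so free two-dimensional motion obeys
#' MSD(t) = 4 D t.
#'
#' @param field a [FieldConfig-class].
#' @param preset a [ConditionPreset-class]; a fraction `pSynaptic` of
#'   receptors is seeded uniformly inside clusters, the rest uniformly in the
#'   field.
#' @param nReceptors number of receptors (>= 1).
#' @param seed integer seed; identical seeds give identical tables.
#' @return a detection table: `data.frame` with columns `frame` (0-based
#'   integer), `x_um`, `y_um`, `true_track_id`, `true_state`
#'   (`"free"`/`"trapped"`) and `true_compartment`
#'   (`"synaptic"`/`"extrasynaptic"`, by the receptor's true position).
#'   The field's frame interval is attached as attribute `frameInterval`.
#' @examples
#' fld <- fieldConfig(clusterCenters = cbind(5, 5), nFrames = 20L)
#' det <- simulateReceptorDetections(fld, controlPreset(), 5, seed = 1)
#' head(det)
#' @export
simulateReceptorDetections <- function(field, preset, nReceptors, seed = 1L) {
  stopifnot(is(field, "FieldConfig"), is(preset, "ConditionPreset"))
  validObject(field); validObject(preset)
  if (length(nReceptors) != 1L || !is.finite(nReceptors) || nReceptors < 1)
    stop("'nReceptors' must be a single integer >= 1")
  nReceptors <- as.integer(nReceptors)

  dt <- field@frameInterval
  nF <- field@nFrames
  w <- field@width; h <- field@height
  syn <- preset@synaptic; ext <- preset@extrasynaptic

  withSeed(seed, {
    ## initial placement: pSynaptic inside clusters (if any), rest uniform
    nClust <- nrow(field@clusterCenters)
    insideInit <- if (nClust > 0L) stats::runif(nReceptors) < preset@pSynaptic
                  else rep(FALSE, nReceptors)
    x <- stats::runif(nReceptors, 0, w)
    y <- stats::runif(nReceptors, 0, h)
    if (any(insideInit)) {
      k <- sum(insideInit)
      ci <- sample.int(nClust, k, replace = TRUE)
      rr <- field@clusterRadius * sqrt(stats::runif(k))
      th <- stats::runif(k, 0, 2 * pi)
      x[insideInit] <- field@clusterCenters[ci, 1] + rr * cos(th)
      y[insideInit] <- field@clusterCenters[ci, 2] + rr * sin(th)
    }

    inCluster <- function(x, y) {
      if (nClust == 0L) return(rep(FALSE, length(x)))
      r2 <- field@clusterRadius^2
      ins <- rep(FALSE, length(x))
      for (ci in seq_len(nClust)) {
        dx <- x - field@clusterCenters[ci, 1]
        dy <- y - field@clusterCenters[ci, 2]
        ins <- ins | (dx * dx + dy * dy <= r2)
      }
      ins
    }

    ## initial state from stationary occupancy of the local switching chain
    compart <- inCluster(x, y)
    kin <- ifelse(compart, syn@kTrapIn, ext@kTrapIn)
    kout <- ifelse(compart, syn@kTrapOut, ext@kTrapOut)
    pTrap <- ifelse(kin + kout > 0, kin / (kin + kout), 0)
    trapped <- stats::runif(nReceptors) < pTrap

    frames <- states <- comps <- xs <- ys <- ids <- vector("list", nF)
    for (f in seq_len(nF)) {
      compart <- inCluster(x, y)
      ## state switching at local rates
      kin <- ifelse(compart, syn@kTrapIn, ext@kTrapIn)
      kout <- ifelse(compart, syn@kTrapOut, ext@kTrapOut)
      u <- stats::runif(nReceptors)
      pSwitch <- ifelse(trapped, 1 - exp(-kout * dt), 1 - exp(-kin * dt))
      trapped <- xor(trapped, u < pSwitch)
      ## Brownian step with state- and compartment-dependent D
      D <- ifelse(trapped,
                  ifelse(compart, syn@dTrapped, ext@dTrapped),
                  ifelse(compart, syn@dFree, ext@dFree))
      sdStep <- sqrt(2 * D * dt)
      x <- x + stats::rnorm(nReceptors, 0, 1) * sdStep
      y <- y + stats::rnorm(nReceptors, 0, 1) * sdStep
      ## reflecting boundaries
      x <- reflectCoord(x, w)
      y <- reflectCoord(y, h)
      compart <- inCluster(x, y)
      ## detection (blinking) and localization noise
      pd <- ifelse(compart, syn@pDetect, ext@pDetect)
      sloc <- ifelse(compart, syn@localizationSigma, ext@localizationSigma)
      det <- stats::runif(nReceptors) < pd
      nd <- sum(det)
      if (nd > 0L) {
        frames[[f]] <- rep.int(f - 1L, nd)
        ids[[f]] <- which(det)
        xs[[f]] <- x[det] + stats::rnorm(nd, 0, sloc[det])
        ys[[f]] <- y[det] + stats::rnorm(nd, 0, sloc[det])
        states[[f]] <- ifelse(trapped[det], "trapped", "free")
        comps[[f]] <- ifelse(compart[det], "synaptic", "extrasynaptic")
      }
    }

    out <- data.frame(
      frame = unlist(frames), x_um = unlist(xs), y_um = unlist(ys),
      true_track_id = unlist(ids), true_state = unlist(states),
      true_compartment = unlist(comps), stringsAsFactors = FALSE
    )
    out <- out[order(out$frame, out$true_track_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "frameInterval") <- dt
    out
  })
}

## Reflect coordinates into [0, L] (handles multiple reflections).
reflectCoord <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}
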