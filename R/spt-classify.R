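#' Classify a trajectory as synaptic or extrasynaptic
#'
#' A trajectory is synaptic when its (localization-noise-bearing) positions
#' fall inside a synaptic cluster for at least `minFrames` frames; otherwise
#' it is extrasynaptic.
#'
#' @param traj data.frame with `x_um`, `y_um` (one track).
#' @param mask a [ClusterMask-class]; there is no default — classification
#'   without a mask is refused.
#' @param minFrames minimum number of in-cluster frames (default 5).
#' @return `"synaptic"` or `"extrasynaptic"`.
#' @examples
#' msk <- clusterMask(cbind(1, 1), radius = 0.3, width = 10, height = 10)
#' traj <- data.frame(frame = 0:5, x_um = 1, y_um = 1)
#' classifyCompartment(traj, msk)
#' @export
classifyCompartment <- function(traj, mask, minFrames = 5L) {
  if (missing(mask) || is.null(mask))
    stop("a cluster mask is required to classify compartments")
  stopifnot(is(mask, "ClusterMask"))
  n <- sum(pointsInMask(traj$x_um, traj$y_um, mask))
  if (n >= minFrames) "synaptic" else "extrasynaptic"
}

#' @rdname classifyCompartment
#' @param x,y coordinates in um.
#' @return for `pointsInMask`: logical vector, TRUE inside any cluster disc.
#' @export
pointsInMask <- function(x, y, mask) {
  if (nrow(mask@centers) == 0L) return(rep(FALSE, length(x)))
  r2 <- mask@radius^2
  ins <- rep(FALSE, length(x))
  for (ci in seq_len(nrow(mask@centers))) {
    dx <- x - mask@centers[ci, 1]; dy <- y - mask@centers[ci, 2]
    ins <- ins | (dx * dx + dy * dy <= r2)
  }
  ins
}

#' Classify mobility from a diffusion coefficient
#'
#' Immobile when `D < threshold` (strict: a coefficient exactly at the
#' threshold is mobile).
#'
#' @param D diffusion coefficient(s), um^2/s.
#' @param threshold immobility cutoff in um^2/s (> 0; default 0.005, a
#'   conventional cutoff near the localization-noise floor for 50-ms
#'   frames).
#' @return character vector, `"immobile"` or `"mobile"`.
#' @export
classifyMobility <- function(D, threshold = 0.005) {
  if (threshold <= 0) stop("'threshold' must be > 0")
  ifelse(D < threshold, "immobile", "mobile")
}
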