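#' Link detections into trajectories
#'
#' Frame-to-frame linking of a detection table. For every new frame, the
#' distances between the last known positions of active tracks and the new
#' detections are computed; candidate links farther than `maxDisp` per
#' elapsed frame are rejected, and the remaining candidates are assigned
#' greedily in order of increasing displacement — which resolves each frame
#' pair towards minimal total displacement while keeping every detection in
#' at most one trajectory. Tracks missing for up to `maxGap` frames stay
#' active with a proportionally enlarged search radius (gap closing).
#'
#' @param detections data.frame with columns `frame` (integer, 0-based,
#'   sorted ascending), `x_um`, `y_um` (any other columns are carried
#'   through).
#' @param maxDisp maximum linking displacement per elapsed frame (um).
#' @param maxGap maximum number of missed frames bridged (>= 0).
#' @return the detection table with an integer `track_id` column; the input
#'   attribute `frameInterval` is preserved.
#' @examples
#' fld <- fieldConfig(nFrames = 20L)
#' det <- simulateReceptorDetections(fld, controlPreset(), 5, seed = 1)
#' tracks <- linkDetections(det, maxDisp = 0.5, maxGap = 2)
#' length(unique(tracks$track_id))
#' @export
linkDetections <- function(detections, maxDisp, maxGap = 2L) {
  if (maxDisp <= 0) stop("'maxDisp' must be > 0")
  if (maxGap < 0) stop("'maxGap' must be >= 0")
  if (nrow(detections) == 0L) {
    detections$track_id <- integer(0)
    return(detections)
  }
  if (is.unsorted(detections$frame))
    stop("'detections' must be sorted by frame")

  frames <- sort(unique(detections$frame))
  idxByFrame <- split(seq_len(nrow(detections)), detections$frame)
  trackId <- integer(nrow(detections))
  nextId <- 1L

  ## active track state: id, last position, last frame
  actId <- integer(0); actX <- numeric(0); actY <- numeric(0)
  actF <- integer(0)

  for (f in frames) {
    rows <- idxByFrame[[as.character(f)]]
    x <- detections$x_um[rows]; y <- detections$y_um[rows]
    nDet <- length(rows)
    assigned <- rep(NA_integer_, nDet)     # index into active tracks

    ## drop tracks that have been dark too long
    live <- actF >= f - 1L - maxGap
    actId <- actId[live]; actX <- actX[live]; actY <- actY[live]
    actF <- actF[live]

    if (length(actId) > 0L && nDet > 0L) {
      dx <- outer(actX, x, "-"); dy <- outer(actY, y, "-")
      dist <- sqrt(dx * dx + dy * dy)
      elapsed <- f - actF                  # >= 1
      lim <- maxDisp * elapsed
      dist[dist > lim] <- NA_real_         # radius grows with the gap
      ## greedy assignment by ascending displacement
      cand <- which(!is.na(dist))
      if (length(cand) > 0L) {
        ord <- cand[order(dist[cand])]
        usedTrack <- logical(length(actId)); usedDet <- logical(nDet)
        ti <- (ord - 1L) %% length(actId) + 1L
        di <- (ord - 1L) %/% length(actId) + 1L
        for (k in seq_along(ord)) {
          if (!usedTrack[ti[k]] && !usedDet[di[k]]) {
            usedTrack[ti[k]] <- TRUE; usedDet[di[k]] <- TRUE
            assigned[di[k]] <- ti[k]
          }
        }
      }
    }

    ## update matched tracks, open new ones for the rest
    for (d in seq_len(nDet)) {
      if (!is.na(assigned[d])) {
        a <- assigned[d]
        trackId[rows[d]] <- actId[a]
        actX[a] <- x[d]; actY[a] <- y[d]; actF[a] <- f
      } else {
        trackId[rows[d]] <- nextId
        actId <- c(actId, nextId); actX <- c(actX, x[d])
        actY <- c(actY, y[d]); actF <- c(actF, f)
        nextId <- nextId + 1L
      }
    }
  }

  detections$track_id <- trackId
  detections
}

#' Split a linked detection table into per-track data.frames
#'
#' @param tracks output of [linkDetections()] (or a table with a `track_id`
#'   column).
#' @param minFrames drop tracks with fewer detections than this.
#' @return named list of per-track data.frames, ordered by frame.
#' @export
splitTracks <- function(tracks, minFrames = 2L) {
  out <- split(tracks, tracks$track_id)
  out <- lapply(out, function(d) d[order(d$frame), , drop = FALSE])
  out[vapply(out, nrow, integer(1)) >= minFrames]
}
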