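#' Time-averaged mean square displacement of one trajectory
#'
#' For each lag `n` (frames), averages the squared displacement over all
#' ordered detection pairs separated by exactly `n` frames (overlapping
#' pairs, maximal data use). Lags with no pairs — e.g. across blinking gaps —
#' are omitted from the output.
#'
#' @param traj data.frame with columns `frame`, `x_um`, `y_um` (one track).
#' @param maxLag largest lag in frames (>= 1).
#' @param frameInterval frame interval in seconds; taken from the
#'   `frameInterval` attribute when `NULL`.
#' @return data.frame with `lag` (frames), `time_s`, `msd` (um^2),
#'   `n_pairs`.
#' @examples
#' traj <- data.frame(frame = 0:5, x_um = c(0, 1, 2, 3, 4, 5), y_um = 0)
#' computeMsd(traj, maxLag = 3, frameInterval = 0.05)  # ballistic: n^2 s^2
#' @export
computeMsd <- function(traj, maxLag = 4L, frameInterval = NULL) {
  if (maxLag < 1L) stop("'maxLag' must be >= 1")
  if (is.null(frameInterval)) frameInterval <- attr(traj, "frameInterval")
  if (is.null(frameInterval))
    stop("'frameInterval' missing and not an attribute of the trajectory")
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 points")
  ord <- order(traj$frame)
  fr <- traj$frame[ord]; x <- traj$x_um[ord]; y <- traj$y_um[ord]
  if (any(duplicated(fr))) stop("trajectory frames must be strictly increasing")

  ## pair detections separated by exactly n frames (gap-aware)
  lagV <- msdV <- timeV <- numeric(0); nV <- integer(0)
  for (n in seq_len(maxLag)) {
    j <- match(fr + n, fr)
    ok <- !is.na(j)
    if (!any(ok)) next
    dx <- x[j[ok]] - x[ok]
    dy <- y[j[ok]] - y[ok]
    lagV <- c(lagV, n)
    msdV <- c(msdV, mean(dx * dx + dy * dy))
    timeV <- c(timeV, n * frameInterval)
    nV <- c(nV, sum(ok))
  }
  data.frame(lag = lagV, time_s = timeV, msd = msdV, n_pairs = nV)
}

#' Diffusion coefficient from the first four MSD points
#'
#' Ordinary least squares of MSD against lag time over the first four lags,
#' with a free intercept that absorbs the localization-noise offset; under
#' two-dimensional free diffusion MSD(t) = 4 D t, so `D = slope / 4`.
#' Negative fitted slopes are clamped to zero and flagged.
#'
#' @param msd output of [computeMsd()]; must contain lags 1 through
#'   `nPoints`.
#' @param nPoints number of initial MSD points used (default 4).
#' @return `D` in um^2/s, with attribute `clamped` (logical) set when a
#'   negative slope was clamped.
#' @examples
#' msd <- data.frame(lag = 1:4, time_s = (1:4) * 0.05,
#'                   msd = 4 * 0.05 * (1:4) * 0.05, n_pairs = 10)
#' estimateDiffusionCoefficient(msd)   # exactly 0.05
#' @export
estimateDiffusionCoefficient <- function(msd, nPoints = 4L) {
  need <- seq_len(nPoints)
  if (!all(need %in% msd$lag))
    stop("MSD must contain lags 1..", nPoints, " (short or gappy track)")
  sel <- msd[match(need, msd$lag), ]
  fit <- stats::lm.fit(cbind(1, sel$time_s), sel$msd)
  slope <- fit$coefficients[2L]
  D <- slope / 4
  clamped <- FALSE
  if (D < 0) { D <- 0; clamped <- TRUE }
  structure(unname(D), clamped = clamped)
}

#' Per-track mobility records for a linked detection table
#'
#' Runs [computeMsd()] and [estimateDiffusionCoefficient()] on every track
#' with at least `minFrames` detections, classifies its compartment against
#' the cluster mask (five-frame co-localization rule) and its mobility
#' against the diffusion threshold.
#'
#' @param tracks linked detection table (see [linkDetections()]).
#' @param mask a [ClusterMask-class]; required for compartment labels.
#' @param frameInterval frame interval (s); from the table attribute when
#'   `NULL`.
#' @param minFrames minimum detections per usable track (default 8, allowing
#'   four lags with at least four pairs each).
#' @param dThreshold immobility threshold in um^2/s (default 0.005).
#' @param nPoints MSD points used in the fit.
#' @return data.frame with `track_id`, `D`, `n_frames`, `compartment`,
#'   `mobility`, `clamped`; the number of tracks skipped as too short and
#'   the thresholds used are attached as attributes `n_skipped`,
#'   `dThreshold`, `minFrames`.
#' @export
mobilityRecords <- function(tracks, mask, frameInterval = NULL,
                            minFrames = 8L, dThreshold = 0.005,
                            nPoints = 4L) {
  if (is.null(frameInterval)) frameInterval <- attr(tracks, "frameInterval")
  if (is.null(frameInterval)) stop("'frameInterval' must be supplied")
  trs <- splitTracks(tracks, minFrames = minFrames)
  nAll <- length(unique(tracks$track_id))
  rows <- lapply(trs, function(tr) {
    msd <- computeMsd(tr, maxLag = nPoints, frameInterval = frameInterval)
    if (!all(seq_len(nPoints) %in% msd$lag)) return(NULL)
    D <- estimateDiffusionCoefficient(msd, nPoints = nPoints)
    data.frame(track_id = tr$track_id[1L], D = as.numeric(D),
               n_frames = nrow(tr),
               compartment = classifyCompartment(tr, mask),
               mobility = classifyMobility(as.numeric(D), dThreshold),
               clamped = attr(D, "clamped"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(track_id = integer(0), D = numeric(0),
                      n_frames = integer(0), compartment = character(0),
                      mobility = character(0), clamped = logical(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- nAll - nrow(out)
  attr(out, "dThreshold") <- dThreshold
  attr(out, "minFrames") <- minFrames
  out
}
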