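## Readers and writers for the exchange formats: detection tables and
## mobility records as CSV, current traces as CSV with a JSON sidecar,
## phase stacks and lifetime maps as multi-page TIFF with a JSON sidecar,
## cluster masks and experiment plans as YAML.

#' Read and write detection tables
#'
#' CSV with columns `frame` (0-based integer), `x_um`, `y_um` and the
#' optional ground-truth columns `true_track_id`, `true_state`,
#' `true_compartment`.
#'
#' @param detections detection table (see [simulateReceptorDetections()]).
#' @param path file path.
#' @param frameInterval frame interval (s) stored alongside on write and
#'   attached on read.
#' @return `readDetectionTable` returns the table with the `frameInterval`
#'   attribute set.
#' @export
writeDetectionTable <- function(detections, path, frameInterval = NULL) {
  if (is.null(frameInterval)) frameInterval <- attr(detections, "frameInterval")
  utils::write.csv(detections, path, row.names = FALSE)
  if (!is.null(frameInterval))
    jsonlite::write_json(list(frameInterval = frameInterval),
                         sidecarPath(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDetectionTable
#' @export
readDetectionTable <- function(path, frameInterval = NULL) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(out)))
    stop("detection table must contain columns: ", paste(need, collapse = ", "))
  sc <- sidecarPath(path)
  if (is.null(frameInterval) && file.exists(sc))
    frameInterval <- jsonlite::read_json(sc)$frameInterval
  attr(out, "frameInterval") <- frameInterval
  out
}

#' Read and write current traces
#'
#' CSV with columns `time_s`, `current_pA`; metadata (protocol name, dt,
#' scheme fixture id, ...) goes to a JSON sidecar `<path>.json`.
#'
#' @param trace a [CurrentTrace-class].
#' @param path file path.
#' @return `readCurrentTrace` returns a [CurrentTrace-class].
#' @export
writeCurrentTrace <- function(trace, path) {
  stopifnot(is(trace, "CurrentTrace"))
  utils::write.csv(data.frame(time_s = traceTimes(trace),
                              current_pA = trace@i),
                   path, row.names = FALSE)
  meta <- trace@metadata
  meta$occupancy <- NULL                      # bulky; not part of the contract
  jsonlite::write_json(c(list(dt = trace@dt, t0 = trace@t0), meta),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCurrentTrace
#' @export
readCurrentTrace <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(d)))
    stop("trace file must contain columns time_s, current_pA")
  dt <- if (nrow(d) >= 2L) stats::median(diff(d$time_s)) else
    stop("trace needs at least two samples")
  rel <- abs(diff(d$time_s) / dt - 1)
  if (any(rel > 1e-6)) stop("trace is not uniformly sampled")
  meta <- list()
  sc <- sidecarPath(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  currentTrace(d$current_pA, dt = meta$dt %||% dt, t0 = d$time_s[1L],
               metadata = meta[setdiff(names(meta), c("dt", "t0"))])
}

#' Read and write phase stacks
#'
#' Multi-page TIFF, one page per phase step in phase order. Pixel values are
#' stored normalized to the stack maximum; the scale factor and the
#' modulation metadata (`modFreq`, `nPhases`, `referenceLifetime`, reference
#' phasor if set) live in the JSON sidecar.
#'
#' @param stack a [PhaseStack-class].
#' @param path file path (`.tif`).
#' @return `readPhaseStack` returns a [PhaseStack-class].
#' @export
writePhaseStack <- function(stack, path) {
  stopifnot(is(stack, "PhaseStack"))
  mx <- max(stack@images, 1e-12)
  pages <- lapply(seq_len(stack@nPhases), function(k)
    stack@images[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(modFreq = stack@modFreq, nPhases = stack@nPhases,
         referenceLifetime = stack@referenceLifetime,
         referencePhase = stack@referencePhase,
         referenceModulation = stack@referenceModulation,
         scale = mx),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhaseStack
#' @export
readPhaseStack <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) stop("phase-stack sidecar missing: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  imgs <- array(NA_real_, c(dim(pages[[1L]])[1:2], length(pages)))
  for (k in seq_along(pages)) imgs[, , k] <- pages[[k]] * meta$scale
  phaseStack(imgs, modFreq = meta$modFreq,
             referenceLifetime = meta$referenceLifetime,
             referencePhase = suppressWarnings(
               as.numeric(meta$referencePhase %||% NA_real_)),
             referenceModulation = suppressWarnings(
               as.numeric(meta$referenceModulation %||% NA_real_)))
}

#' Write a lifetime map as 32-bit float TIFF (ns)
#'
#' Invalid pixels are written as 0; the valid mask and scale are stored in
#' the JSON sidecar.
#'
#' @param map a [LifetimeMap-class].
#' @param path file path.
#' @export
writeLifetimeMap <- function(map, path) {
  stopifnot(is(map, "LifetimeMap"))
  tau <- map@tauPhi
  tau[!map@valid] <- 0
  mx <- max(tau, 1e-12)
  tiff::writeTIFF(tau / mx, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = mx, n_valid = sum(map@valid),
                            metadata = map@metadata),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write cluster masks (YAML disc lists)
#'
#' @param mask a [ClusterMask-class].
#' @param path file path (`.yaml`).
#' @return `readClusterMask` returns a [ClusterMask-class].
#' @export
writeClusterMask <- function(mask, path) {
  stopifnot(is(mask, "ClusterMask"))
  yaml::write_yaml(list(
    width = mask@width, height = mask@height, radius = mask@radius,
    centers = lapply(seq_len(nrow(mask@centers)), function(i)
      as.list(setNames(mask@centers[i, ], c("x", "y"))))
  ), path)
  invisible(path)
}

#' @rdname writeClusterMask
#' @export
readClusterMask <- function(path) {
  d <- yaml::read_yaml(path)
  for (k in c("width", "height", "radius", "centers"))
    if (is.null(d[[k]])) stop("cluster mask file lacks field '", k, "'")
  centers <- do.call(rbind, lapply(d$centers, function(p) c(p$x, p$y)))
  if (is.null(centers)) centers <- matrix(numeric(0), ncol = 2)
  clusterMask(centers, radius = d$radius, width = d$width, height = d$height)
}

sidecarPath <- function(path) paste0(path, ".json")
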