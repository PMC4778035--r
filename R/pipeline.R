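## End-to-end experiment plans: YAML-configured, seeded, stage-structured
## runs binding the simulators to the analysis stages.

#' Run an experiment plan
#'
#' Executes the selected stages of a YAML experiment plan in dependency
#' order: `simulate-spt` / `analyze-spt`, `simulate-current` /
#' `analyze-current`, `simulate-mepsc` / `analyze-mepsc`, `simulate-flim` /
#' `analyze-flim` and `report`. Every stage writes into its own
#' sub-directory of `outDir`; all outputs are stamped with the plan hash and
#' root seed, and re-running an identical plan reproduces identical outputs.
#' Existing stage directories are refused unless `force = TRUE`. Plan
#' validation failures (missing or malformed keys, missing stage inputs)
#' abort before any computation, naming the offending key.
#'
#' @param plan path to a YAML plan or an equivalent named list. Top-level
#'   keys: `name`, `seed`, and per-stage parameter blocks `spt`, `ephys`,
#'   `mepsc`, `flim` (only blocks for requested stages are required).
#' @param outDir output directory (created if absent).
#' @param stages character vector of stages to run; default all stages whose
#'   parameter block is present.
#' @param force overwrite existing stage outputs?
#' @return named list of per-stage output paths, invisibly.
#' @export
runPipeline <- function(plan, outDir, stages = NULL, force = FALSE) {
  if (is.character(plan)) plan <- yaml::read_yaml(plan)
  validatePlan(plan)
  allStages <- c("simulate-spt", "analyze-spt", "simulate-current",
                 "analyze-current", "simulate-mepsc", "analyze-mepsc",
                 "simulate-flim", "analyze-flim", "report")
  if (is.null(stages)) {
    stages <- character(0)
    if (!is.null(plan$spt)) stages <- c(stages, "simulate-spt", "analyze-spt")
    if (!is.null(plan$ephys)) stages <- c(stages, "simulate-current", "analyze-current")
    if (!is.null(plan$mepsc)) stages <- c(stages, "simulate-mepsc", "analyze-mepsc")
    if (!is.null(plan$flim)) stages <- c(stages, "simulate-flim", "analyze-flim")
    stages <- c(stages, "report")
  }
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- allStages[allStages %in% stages]   # dependency order

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(plan = plan$name, plan_hash = planHash(plan),
                seed = plan$seed, package_version =
                  as.character(utils::packageVersion("synaptiq")))
  paths <- list()
  for (st in stages) {
    sd <- file.path(outDir, st)
    if (dir.exists(sd) && length(list.files(sd)) > 0L && !force)
      stop("stage output exists (use force = TRUE to overwrite): ", sd)
    unlink(sd, recursive = TRUE)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    paths[[st]] <- switch(st,
      "simulate-spt" = stageSimulateSpt(plan, sd, stamp),
      "analyze-spt" = stageAnalyzeSpt(plan, file.path(outDir, "simulate-spt"),
                                      sd, stamp),
      "simulate-current" = stageSimulateCurrent(plan, sd, stamp),
      "analyze-current" = stageAnalyzeCurrent(plan,
                                              file.path(outDir, "simulate-current"),
                                              sd, stamp),
      "simulate-mepsc" = stageSimulateMepsc(plan, sd, stamp),
      "analyze-mepsc" = stageAnalyzeMepsc(plan,
                                          file.path(outDir, "simulate-mepsc"),
                                          sd, stamp),
      "simulate-flim" = stageSimulateFlim(plan, sd, stamp),
      "analyze-flim" = stageAnalyzeFlim(plan,
                                        file.path(outDir, "simulate-flim"),
                                        sd, stamp),
      "report" = stageReport(outDir, sd, stamp)
    )
  }
  invisible(paths)
}

validatePlan <- function(plan) {
  if (!is.list(plan)) stop("plan must be a list or a YAML file path")
  for (k in c("name", "seed"))
    if (is.null(plan[[k]])) stop("plan is missing required key '", k, "'")
  if (!is.numeric(plan$seed)) stop("plan key 'seed' must be numeric")
  if (!is.null(plan$spt)) {
    for (k in c("conditions", "n_cells", "receptors_per_cell"))
      if (is.null(plan$spt[[k]]))
        stop("plan is missing required key 'spt.", k, "'")
  }
  if (!is.null(plan$ephys) && is.null(plan$ephys$schemes))
    stop("plan is missing required key 'ephys.schemes'")
  if (!is.null(plan$mepsc) && is.null(plan$mepsc$genotypes))
    stop("plan is missing required key 'mepsc.genotypes'")
  if (!is.null(plan$flim) && is.null(plan$flim$conditions))
    stop("plan is missing required key 'flim.conditions'")
  invisible(TRUE)
}

writeStamp <- function(dir, stamp, extra = list()) {
  jsonlite::write_json(c(stamp, extra), file.path(dir, "stage.json"),
                       auto_unbox = TRUE, digits = NA)
}

stageSimulateSpt <- function(plan, sd, stamp) {
  p <- plan$spt
  field <- defaultField(nFrames = as.integer(p$n_frames %||% 200L))
  writeClusterMask(fieldMask(field), file.path(sd, "cluster_mask.yaml"))
  for (cond in p$conditions) {
    for (cell in seq_len(p$n_cells)) {
      det <- simulateReceptorDetections(
        field, getPreset(cond), p$receptors_per_cell,
        seed = deriveSeed(plan$seed, "spt", cond, cell))
      writeDetectionTable(det,
        file.path(sd, sprintf("detections_%s_cell%02d.csv", cond, cell)),
        frameInterval = field@frameInterval)
    }
  }
  writeStamp(sd, stamp, list(conditions = p$conditions,
                             n_cells = p$n_cells))
  sd
}

stageAnalyzeSpt <- function(plan, simDir, sd, stamp) {
  p <- plan$spt
  maskPath <- file.path(simDir, "cluster_mask.yaml")
  if (!file.exists(maskPath))
    stop("analyze-spt input missing: cluster mask not found at ", maskPath)
  mask <- readClusterMask(maskPath)
  recs <- list()
  for (cond in p$conditions) {
    for (cell in seq_len(p$n_cells)) {
      f <- file.path(simDir, sprintf("detections_%s_cell%02d.csv", cond, cell))
      if (!file.exists(f))
        stop("analyze-spt input missing: detection table not found at ", f)
      det <- readDetectionTable(f)
      tracks <- linkDetections(det, maxDisp = p$max_disp %||% 0.5,
                               maxGap = as.integer(p$max_gap %||% 2L))
      r <- mobilityRecords(tracks, mask,
                           dThreshold = p$d_threshold %||% 0.005)
      if (nrow(r)) { r$condition <- cond; r$cell <- cell }
      recs[[paste(cond, cell)]] <- r
    }
  }
  records <- do.call(rbind, recs)
  attr(records, "dThreshold") <- plan$spt$d_threshold %||% 0.005
  utils::write.csv(records, file.path(sd, "mobility_records.csv"),
                   row.names = FALSE)
  summ <- summarizeMobility(records)
  jsonlite::write_json(summ, file.path(sd, "mobility_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeStamp(sd, stamp, list(d_threshold = plan$spt$d_threshold %||% 0.005))
  sd
}

stageSimulateCurrent <- function(plan, sd, stamp) {
  p <- plan$ephys
  dt <- p$dt %||% 1e-4
  intervals <- p$recovery_intervals %||%
    c(20, 50, 100, 200, 300, 400, 500, 750, 1000, 3000)
  for (sch in p$schemes) {
    scheme <- getScheme(sch)
    writeCurrentTrace(simulateGatingResponse(scheme, pulseProtocol(1), dt = dt),
                      file.path(sd, sprintf("pulse1ms_%s.csv", sch)))
    writeCurrentTrace(simulateGatingResponse(scheme,
                                             pulseProtocol(1000, tailMs = 100),
                                             dt = dt),
                      file.path(sd, sprintf("pulse1s_%s.csv", sch)))
    for (ipi in intervals)
      writeCurrentTrace(simulateGatingResponse(scheme,
                                               pairedPulseProtocol(ipi),
                                               dt = dt),
                        file.path(sd, sprintf("paired_%s_%04d.csv", sch, ipi)))
  }
  writeStamp(sd, stamp, list(schemes = p$schemes, dt = dt,
                             recovery_intervals = intervals))
  sd
}

stageAnalyzeCurrent <- function(plan, simDir, sd, stamp) {
  p <- plan$ephys
  intervals <- p$recovery_intervals %||%
    c(20, 50, 100, 200, 300, 400, 500, 750, 1000, 3000)
  out <- list()
  for (sch in p$schemes) {
    sh <- readCurrentTrace(file.path(simDir, sprintf("pulse1ms_%s.csv", sch)))
    lo <- readCurrentTrace(file.path(simDir, sprintf("pulse1s_%s.csv", sch)))
    fsS <- extractFeatures(sh, applicationWindow = c(0.010, 0.011))
    fsL <- extractFeatures(lo, applicationWindow = c(0.010, 1.010))
    traces <- lapply(intervals, function(ipi)
      readCurrentTrace(file.path(simDir, sprintf("paired_%s_%04d.csv", sch, ipi))))
    rec <- recoveryAnalysis(traces, intervals)
    out[[sch]] <- list(
      rise_20_80_ms = fsS$rise_20_80, decay_90_10_ms = fsS$decay_90_10,
      tau_des_ms = fsL$tau_des, steady_state_pct = fsL$steady_state_pct,
      tau_recovery_ms = rec$tau_recovery, recovery_floor = rec$recovery_floor,
      recovery_ratio = rec$ratio, recovery_intervals_ms = rec$intervals_ms)
  }
  jsonlite::write_json(out, file.path(sd, "current_features.json"),
                       auto_unbox = TRUE, digits = NA)
  writeStamp(sd, stamp)
  sd
}

stageSimulateMepsc <- function(plan, sd, stamp) {
  p <- plan$mepsc
  for (g in p$genotypes) {
    sim <- simulateMepscTrace(mepscPreset(g, duration = p$duration %||% 60),
                              seed = deriveSeed(plan$seed, "mepsc", g))
    writeCurrentTrace(sim$trace, file.path(sd, sprintf("mepsc_%s.csv", g)))
    utils::write.csv(sim$events, file.path(sd, sprintf("events_%s.csv", g)),
                     row.names = FALSE)
  }
  writeStamp(sd, stamp, list(genotypes = p$genotypes))
  sd
}

stageAnalyzeMepsc <- function(plan, simDir, sd, stamp) {
  p <- plan$mepsc
  out <- list()
  for (g in p$genotypes) {
    f <- file.path(simDir, sprintf("mepsc_%s.csv", g))
    if (!file.exists(f)) stop("analyze-mepsc input missing: ", f)
    tr <- readCurrentTrace(f)
    det <- detectMepscs(tr, thresholdSd = p$threshold_sd %||% 5)
    out[[g]] <- det$summary
    utils::write.csv(det$events,
                     file.path(sd, sprintf("detected_events_%s.csv", g)),
                     row.names = FALSE)
  }
  jsonlite::write_json(out, file.path(sd, "mepsc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeStamp(sd, stamp)
  sd
}

stageSimulateFlim <- function(plan, sd, stamp) {
  p <- plan$flim
  size <- as.integer(p$size %||% 32L)
  intensity <- p$intensity %||% 2000
  instrPhase <- p$instrument_phase %||% 0.3
  ## one shared reference acquisition per run
  ref <- simulateFlimStack(fluoresceinTruth(size, size, intensity = 5000),
                           photonNoise = isTRUE(p$photon_noise),
                           seed = deriveSeed(plan$seed, "flim", "ref"),
                           instrumentPhase = instrPhase)
  writePhaseStack(ref, file.path(sd, "reference.tif"))
  for (cond in p$conditions) {
    pre <- flimPreset(cond, "spine")
    ph <- fretMixturePhasor(pre$donorTau, pre$quenchedTau, pre$fretFraction)
    stk <- simulatePhasorStack(matrix(ph$phi, size, size),
                               matrix(ph$m, size, size),
                               intensity = intensity,
                               photonNoise = isTRUE(p$photon_noise),
                               seed = deriveSeed(plan$seed, "flim", cond),
                               instrumentPhase = instrPhase)
    writePhaseStack(stk, file.path(sd, sprintf("stack_%s_spine.tif", cond)))
  }
  writeStamp(sd, stamp, list(conditions = p$conditions, size = size))
  sd
}

stageAnalyzeFlim <- function(plan, simDir, sd, stamp) {
  p <- plan$flim
  refPath <- file.path(simDir, "reference.tif")
  if (!file.exists(refPath))
    stop("analyze-flim input missing: reference stack not found at ", refPath)
  ref <- readPhaseStack(refPath)
  out <- list()
  for (cond in p$conditions) {
    f <- file.path(simDir, sprintf("stack_%s_spine.tif", cond))
    if (!file.exists(f)) stop("analyze-flim input missing: ", f)
    stk <- readPhaseStack(f)
    map <- computeLifetimeMap(stk, ref)
    writeLifetimeMap(map, file.path(sd, sprintf("lifetime_%s_spine.tif", cond)))
    rois <- list(spine = matrix(TRUE, nrow(map@tauPhi), ncol(map@tauPhi)))
    out[[cond]] <- summarizeRois(map, rois)
  }
  jsonlite::write_json(out, file.path(sd, "roi_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeStamp(sd, stamp)
  sd
}

stageReport <- function(outDir, sd, stamp) {
  report <- list(stamp = stamp)
  grab <- function(stage, file) {
    f <- file.path(outDir, stage, file)
    if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE) else NULL
  }
  report$mobility <- grab("analyze-spt", "mobility_summary.json")
  report$currents <- grab("analyze-current", "current_features.json")
  report$mepsc <- grab("analyze-mepsc", "mepsc_summary.json")
  report$flim <- grab("analyze-flim", "roi_summary.json")
  jsonlite::write_json(report, file.path(sd, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  sd
}
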