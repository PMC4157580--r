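# Session container I/O (plain-text directory: CSV arrays + YAML metadata)
# and the end-to-end pipeline: simulate -> preprocess -> detect -> geometry
# -> decode -> dynamics -> phase.

containerVersion <- "1"

# CSV writer for numeric tables at full double precision (%.17g), so that a
# write/read cycle reproduces the arrays bit for bit; fread parses the full
# precision back.
writeNumericCsv <- function(x, file) {
  x <- as.data.frame(x)
  if (nrow(x) == 0L) {
    writeLines(paste(names(x), collapse = ","), file)
    return(invisible(file))
  }
  cols <- vapply(seq_along(x), function(j) {
    col <- x[[j]]
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(x)))
  cols <- matrix(cols, nrow = nrow(x))
  writeLines(c(paste(names(x), collapse = ","),
               do.call(paste, c(split(cols, col(cols)), sep = ","))), file)
}

#' Write a session to a plain-text container directory
#'
#' Serializes a [RecordingSession-class] as a directory of delimited text
#' files plus a YAML metadata block: `meta.yaml`, `lfp.csv` (samples x
#' channels), `torque.csv`, `emg.csv`, `spikes.csv` (unit, time),
#' `trials.csv`, and ground-truth event tables
#' (`groundtruth_events.csv`, `groundtruth_kcomplexes.csv`,
#' `groundtruth_meta.yaml`, `groundtruth_mixing.csv`). Doubles are written
#' in round-trippable precision, so a write/read cycle reproduces the
#' arrays bit for bit.
#'
#' @param session a [RecordingSession-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "RecordingSession"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) writeNumericCsv(x, file.path(path, f))
  meta <- list(container_version = containerVersion,
               package_version = as.character(packageVersion("lfpdyn")),
               condition = session@condition,
               sample_rate = session@lfp@sampleRate,
               channel_area = as.list(session@lfp@channelArea),
               reference = session@lfp@reference,
               n_units = length(session@spikes),
               config = session@config[!vapply(session@config, is.null, TRUE)])
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  fw(t(session@lfp@samples), "lfp.csv")
  if (!is.null(session@kinematics)) fw(session@kinematics@torque, "torque.csv")
  if (ncol(session@emg)) fw(session@emg, "emg.csv")
  if (length(session@spikes)) {
    sp <- data.frame(unit = rep(seq_along(session@spikes),
                                lengths(session@spikes)),
                     time = unlist(session@spikes))
    fw(sp, "spikes.csv")
  }
  fw(session@trialBounds, "trials.csv")
  gt <- session@groundTruth
  if (!is.null(gt)) {
    fw(gt@submovements, "groundtruth_events.csv")
    fw(data.frame(time = gt@kcomplexes), "groundtruth_kcomplexes.csv")
    fw(gt@mixingMatrix, "groundtruth_mixing.csv")
    yaml::write_yaml(list(preferred_phases = as.list(gt@preferredPhases)),
                     file.path(path, "groundtruth_meta.yaml"))
  }
  invisible(path)
}

#' Read a session container directory
#'
#' Inverse of [writeSession()]. The large ground-truth time series (latent
#' phase/amplitude/trajectory) are not serialized; only the event tables,
#' preferred phases and mixing matrix are restored.
#'
#' @param path container directory.
#' @return A [RecordingSession-class].
#' @export
readSession <- function(path) {
  metaFile <- file.path(path, "meta.yaml")
  if (!file.exists(metaFile)) stop("not a session container: missing meta.yaml")
  meta <- yaml::read_yaml(metaFile)
  if (!identical(as.character(meta$container_version), containerVersion))
    stop("container version ", meta$container_version,
         " does not match this package (", containerVersion,
         "); no migration path")
  for (required in c("lfp.csv", "trials.csv"))
    if (!file.exists(file.path(path, required)))
      stop("container schema error: missing required array ", required)
  fr <- function(f) {
    m <- as.matrix(data.table::fread(file.path(path, f)))
    dimnames(m) <- NULL
    m
  }
  lfp <- multichannelRecording(t(fr("lfp.csv")), meta$sample_rate,
                               unlist(meta$channel_area), meta$reference)
  kin <- NULL
  if (file.exists(file.path(path, "torque.csv")))
    kin <- computeRadialSpeed(fr("torque.csv"), meta$sample_rate)
  emg <- if (file.exists(file.path(path, "emg.csv"))) fr("emg.csv") else matrix(0, 0, 0)
  spikes <- list()
  if (file.exists(file.path(path, "spikes.csv"))) {
    sp <- data.table::fread(file.path(path, "spikes.csv"))
    spikes <- lapply(seq_len(max(meta$n_units, max(sp$unit))),
                     function(u) sort(sp$time[sp$unit == u]))
  }
  gt <- NULL
  if (file.exists(file.path(path, "groundtruth_events.csv"))) {
    gmeta <- yaml::read_yaml(file.path(path, "groundtruth_meta.yaml"))
    kc <- data.table::fread(file.path(path, "groundtruth_kcomplexes.csv"))
    gt <- new("GroundTruth",
              latentPhase = numeric(), latentAmplitude = numeric(),
              submovements = as.data.frame(
                data.table::fread(file.path(path, "groundtruth_events.csv"))),
              kcomplexes = if (nrow(kc)) kc$time else numeric(),
              preferredPhases = unlist(gmeta$preferred_phases),
              mixingMatrix = fr("groundtruth_mixing.csv"),
              latents = matrix(0, 0, 3))
  }
  new("RecordingSession", lfp = lfp, kinematics = kin, emg = emg,
      spikes = spikes, condition = meta$condition,
      trialBounds = fr("trials.csv"),
      config = if (is.null(meta$config)) list() else meta$config,
      groundTruth = gt)
}

pipelineConfigKeys <- c("simulation", "seed", "outputDir", "sedationPair",
                        "nShuffles", "nullReps", "nullDuration",
                        "nullChannels", "stages", "nComponents")

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates a full run on synthetic data: simulate a task session (and
#' optionally a paired sedation session sharing channel phases), preprocess
#' (5 Hz low-pass, within-area mean referencing, PCA, projection), detect
#' submovements (and K complexes), compute trajectory geometry and
#' speed-group areal velocities, run leave-one-out kinematic decoding (with
#' optional shuffle thresholds), fit the trace-zero dynamics model (delta
#' and beta bands, cross-condition generalization, white-noise null), and
#' compute phase statistics (per-channel event-relative phases,
#' cross-state circular correlation, spike preferred phases with Rayleigh
#' tests, speed-LFP coherence).
#'
#' @param config a YAML file path or a list with keys: `simulation` (list of
#'   [simulationConfig()] overrides), `seed`, `outputDir` (optional; session
#'   containers and a JSON report are written there), `sedationPair`
#'   (logical, default TRUE), `nShuffles` (default 0 = skip), `nullReps`
#'   (default 0 = skip), `nullDuration`, `nullChannels`, `nComponents`
#'   (default 3). Unknown keys are an error.
#' @return A `RunReport`: a nested list of per-stage numeric summaries with
#'   stage timings, also written as `report.json` under `outputDir` when
#'   given.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), pipelineConfigKeys)
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(pipelineConfigKeys, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  simArgs <- if (is.null(config$simulation)) list() else config$simulation
  simArgs$seed <- seed
  cfg <- do.call(simulationConfig, simArgs)
  sedationPair <- !isFALSE(config$sedationPair)
  nComp <- if (is.null(config$nComponents)) 3L else config$nComponents
  report <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## simulate
  task <- simulateTaskSession(cfg)
  sed <- if (sedationPair) simulateSedationSession(cfg) else NULL
  report$simulate <- list(
    nSubmovementsTrue = nrow(task@groundTruth@submovements),
    nKComplexesTrue = if (sedationPair) length(sed@groundTruth@kcomplexes) else NA,
    duration = cfg$duration, seconds = tic() - t0)

  ## preprocess
  t0 <- tic()
  taskDelta <- meanReference(lowpassDelta(task@lfp))
  basis <- fitPCA(taskDelta, nComp, sourceCondition = "task")
  traj <- projectRecording(taskDelta, basis)
  traj2 <- stateTrajectory(stateX(traj)[, 1:2], sampleRate(traj))
  report$preprocess <- list(
    varianceExplained = as.numeric(varianceExplained(basis)),
    seconds = tic() - t0)

  ## detect
  t0 <- tic()
  events <- detectSubmovements(task@kinematics, trialBounds = task@trialBounds)
  iac <- intervalAutocorrelation(events$peakTime, task@trialBounds)
  report$detect <- list(
    nSubmovements = nrow(events),
    intervalModeMs = 1000 * iac$lag[which.max(iac$ratio)],
    seconds = tic() - t0)

  ## geometry
  t0 <- tic()
  groups <- binEventsBySpeed(events)
  av <- eventArealVelocityMatrix(traj, events)
  events <- events[av$kept, , drop = FALSE]
  groups <- groups[av$kept]
  grpMag <- vapply(sort(unique(groups)), function(g)
    mean(sqrt(rowSums(av$v[groups == g, , drop = FALSE]^2))), numeric(1))
  report$geometry <- list(
    speedGroupArealVelocity = grpMag,
    monotoneGroups = all(diff(grpMag) > 0),
    seconds = tic() - t0)

  ## decode
  t0 <- tic()
  dec <- looDecode(av$v, events$peakSpeed, events$direction)
  report$decode <- list(codSpeed = dec@codSpeed,
                        codDirection = dec@codDirection,
                        nUndecoded = dec@nUndecoded)
  if (!is.null(config$nShuffles) && config$nShuffles > 0) {
    sh <- shuffleSignificance(av$v, events$peakSpeed, events$direction,
                              nShuffles = config$nShuffles, seed = seed + 1L)
    report$decode$shuffleThresholdSpeed <- sh$thresholdSpeed
    report$decode$shuffleThresholdDirection <- sh$thresholdDirection
  }
  report$decode$seconds <- tic() - t0

  ## dynamics
  t0 <- tic()
  model <- fitDynamics(traj2, sourceCondition = "task")
  report$dynamics <- list(codFit = model@codFit,
                          modelFrequencyHz = modelFrequency(model),
                          correlationFrequencyHz = correlationFrequency(traj2))
  taskBeta <- meanReference(bandpassBeta(task@lfp))
  basisBeta <- fitPCA(taskBeta, 2L, sourceCondition = "task")
  trajBeta <- projectRecording(taskBeta, basisBeta, band = "beta")
  report$dynamics$codFitBeta <- fitDynamics(trajBeta, "task")@codFit
  if (sedationPair) {
    sedDelta <- meanReference(lowpassDelta(sed@lfp))
    sedTraj <- projectRecording(sedDelta, basis)
    sedTraj2 <- stateTrajectory(stateX(sedTraj)[, 1:2], sampleRate(sedTraj))
    report$dynamics$codGeneralization <- generalizeDynamics(model, sedTraj2)
    report$dynamics$codSedationFit <-
      fitDynamics(sedTraj2, sourceCondition = "sedation")@codFit
  }
  if (!is.null(config$nullReps) && config$nullReps > 0) {
    nullRes <- whiteNoiseNull(
      nChannels = if (is.null(config$nullChannels)) 10L else config$nullChannels,
      duration = if (is.null(config$nullDuration)) 600 else config$nullDuration,
      sampleRate = cfg$sampleRate, nReps = config$nullReps, seed = seed + 2L)
    report$dynamics$nullP95 <- nullRes$p95
  }
  report$dynamics$seconds <- tic() - t0

  ## phase
  t0 <- tic()
  smPhases <- apply(lfpSamples(taskDelta), 1L, function(ch)
    as.numeric(suppressWarnings(eventRelativePhase(
      eventTriggeredAverage(ch, events$peakTime, cfg$sampleRate)))))
  report$phase <- list(nChannels = length(smPhases))
  if (sedationPair) {
    kcs <- detectKComplexes(sed@lfp)
    report$phase$nKComplexesDetected <- nrow(kcs)
    if (nrow(kcs) >= 2) {
      sedDelta <- meanReference(lowpassDelta(sed@lfp))
      kcPhases <- apply(lfpSamples(sedDelta), 1L, function(ch)
        as.numeric(suppressWarnings(eventRelativePhase(
          eventTriggeredAverage(ch, kcs$peakTime, cfg$sampleRate)))))
      cc <- circularCorrelation(smPhases, kcPhases)
      report$phase$rhoCC <- cc$rho
      report$phase$rhoCCp <- cc$p
    }
  }
  rot <- rotatePlaneToSpeedPhase(traj2, events$peakTime)
  prefs <- lapply(task@spikes, function(sp)
    tryCatch(preferredPhase(sp, rot$traj), error = function(e) NULL))
  okPref <- !vapply(prefs, is.null, TRUE)
  report$phase$nUnitsPhaseLocked <- sum(vapply(prefs[okPref],
                                               function(p) p$p < 0.05, TRUE))
  report$phase$meanPreferredPhase <- if (any(okPref))
    atan2(mean(sin(vapply(prefs[okPref], `[[`, numeric(1), "meanPhase"))),
          mean(cos(vapply(prefs[okPref], `[[`, numeric(1), "meanPhase")))) else NA
  nSamp <- ncol(lfpSamples(task@lfp))
  if (nSamp >= 2L * 2048L) {
    coh <- coherenceSpectrum(task@kinematics@radialSpeed, stateX(traj)[, 2],
                             cfg$sampleRate)
    report$phase$coherencePeakHz <- coh$freq[which.max(coh$coherence)]
  }
  report$phase$seconds <- tic() - t0

  ## serialize
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeSession(task, file.path(config$outputDir, "session_task"))
    if (sedationPair)
      writeSession(sed, file.path(config$outputDir, "session_sedation"))
    data.table::fwrite(events, file.path(config$outputDir, "submovements.csv"))
    jsonlite::write_json(report, file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run report\n")
  for (stage in names(x)) {
    cat(sprintf("  %s:\n", stage))
    vals <- x[[stage]]
    for (k in names(vals)) {
      v <- vals[[k]]
      cat(sprintf("    %-28s %s\n", k,
                  paste(vapply(v, function(z)
                    if (is.numeric(z)) sprintf("%.4g", z) else as.character(z),
                    character(1)), collapse = " ")))
    }
  }
  invisible(x)
}
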