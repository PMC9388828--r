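## End-to-end orchestration: simulate or load -> preprocess -> per-epoch
## time-frequency PTE map -> point A -> adjacency -> node metrics ->
## power compensation -> aggregation -> zone statistics, with CSV outputs,
## a JSON manifest and a log file.

#' Assemble a run configuration
#'
#' Either a simulation block (a [SimConfig-class]) or the three input
#' paths (EDF recording, `channel,zone` labels CSV, `marker_seconds`
#' markers CSV) must be provided. Defaults reproduce the reference
#' analysis settings: 200 Hz, 0.5-66.7 Hz band-pass, 60 Hz notch, 3-65 Hz
#' in 2-Hz steps, 500-ms window with 100-ms step, 70% threshold.
#'
#' @param simulation a [SimConfig-class], or `NULL` for real-data mode.
#' @param edfPath,zonesPath,markersPath input files for real-data mode.
#' @param targetFs,low,high,notch preprocessing settings.
#' @param freqs analysis frequencies (Hz).
#' @param windowMs,stepMs sliding-window settings (ms).
#' @param thresholdQ proportional threshold (0.30 / 0.50 / 0.70 supported).
#' @param nCycles Morlet cycles.
#' @param epochDuration epoch length (s).
#' @param useCompensated run zone statistics on compensated parameters.
#' @param seed global seed; overrides the simulation block's seed.
#' @param outdir output directory; `NULL` for tempdir.
#' @return A named list of class `ezpteRunConfig`.
#' @export
runConfig <- function(simulation = simConfig(), edfPath = NULL,
                      zonesPath = NULL, markersPath = NULL,
                      targetFs = 200, low = 0.5, high = 66.7, notch = 60,
                      freqs = seq(3, 65, by = 2), windowMs = 500,
                      stepMs = 100, thresholdQ = 0.70, nCycles = 7,
                      epochDuration = 10, useCompensated = TRUE,
                      seed = NULL, outdir = NULL) {
  if (is.null(simulation) && is.null(edfPath))
    stop("either a simulation block or input paths must be provided")
  if (!is.null(simulation) && !is.null(seed))
    simulation@seed <- as.integer(seed)
  cfg <- list(simulation = simulation, edfPath = edfPath,
              zonesPath = zonesPath, markersPath = markersPath,
              targetFs = targetFs, low = low, high = high, notch = notch,
              freqs = freqs, windowMs = windowMs, stepMs = stepMs,
              thresholdQ = thresholdQ, nCycles = nCycles,
              epochDuration = epochDuration,
              useCompensated = useCompensated,
              seed = if (is.null(seed) && !is.null(simulation))
                simulation@seed else seed,
              outdir = outdir)
  class(cfg) <- "ezpteRunConfig"
  cfg
}

#' Load a recording plus side-car zone labels and markers
#'
#' @param edfPath EDF recording.
#' @param zonesPath CSV with columns `channel, zone`.
#' @param markersPath CSV with column `marker_seconds`.
#' @return `list(recording, zones, markers)`.
#' @export
loadDataset <- function(edfPath, zonesPath, markersPath) {
  for (p in c(edfPath, zonesPath, markersPath))
    if (!file.exists(p))
      stop("input file not found: '", p, "'. Real-data mode needs the EDF ",
           "recording plus zone-label and marker CSVs; check the paths in ",
           "the run configuration.")
  recording <- readEdf(edfPath)
  zonesDf <- utils::read.csv(zonesPath)
  if (!all(c("channel", "zone") %in% colnames(zonesDf)))
    stop("zones CSV must have columns 'channel' and 'zone'")
  markersDf <- utils::read.csv(markersPath)
  if (!"marker_seconds" %in% colnames(markersDf))
    stop("markers CSV must have a 'marker_seconds' column")
  zones <- zonesDf$zone[match(channelLabels(recording), zonesDf$channel)]
  if (any(is.na(zones)))
    stop("zones CSV does not cover every channel in the EDF")
  list(recording = recording, zones = as.character(zones),
       markers = markersDf$marker_seconds)
}

#' Per-epoch network analysis
#'
#' For every epoch: Morlet decomposition, TF synchrony map, point-A
#' selection, 500-ms analysis window, PTE adjacency with proportional
#' threshold, the seven node metrics, and per-electrode maximum power at
#' the point-A frequency.
#'
#' @param epochs an [EpochSet-class] of preprocessed epochs.
#' @param freqs analysis frequencies (Hz).
#' @param params a [PTEParams-class].
#' @param thresholdQ proportional threshold.
#' @param nCycles Morlet cycles.
#' @return `list(perEpochMetrics, perEpochPower, pointAs)` where
#'   `pointAs` is a data.frame with `time` and `freq` per epoch.
#' @export
analyzeEpochs <- function(epochs, freqs = seq(3, 65, by = 2),
                          params = pteParams(), thresholdQ = 0.70,
                          nCycles = 7) {
  stopifnot(is(epochs, "EpochSet"))
  nE <- nEpochs(epochs)
  nc <- dim(epochs@epochs)[1]
  perEpochMetrics <- vector("list", nE)
  perEpochPower <- matrix(0, nrow = nE, ncol = nc,
                          dimnames = list(NULL, channelLabels(epochs)))
  pointAs <- data.frame(time = numeric(nE), freq = numeric(nE))
  for (k in seq_len(nE)) {
    tfd <- morletDecompose(epochs, freqs = freqs, nCycles = nCycles, i = k)
    map <- tfSynchronyMap(tfd, params)
    pa <- pointA(map)
    pointAs$time[k] <- pa["time"]; pointAs$freq[k] <- pa["freq"]
    win <- analysisWindow(pa["time"], samplingRate(epochs),
                          params@windowMs, dim(epochs@epochs)[2])
    adj <- buildAdjacency(tfd, win, pa["freq"], params, thresholdQ)
    perEpochMetrics[[k]] <- nodeMetrics(adj)
    for (ch in seq_len(nc))
      perEpochPower[k, ch] <- maxPower(tfd, ch, win, pa["freq"])
  }
  list(perEpochMetrics = perEpochMetrics, perEpochPower = perEpochPower,
       pointAs = pointAs)
}

#' Run the full pipeline
#'
#' Executes simulate/load, preprocessing, the per-epoch network analysis,
#' power-compensated aggregation and zone statistics, writing
#' `electrode_metrics.csv`, `comparison_table.csv`,
#' `classification_report.csv`, `boxplot_summary.csv`, `point_a.csv`, a
#' JSON `manifest.json` (settings, seed, versions, warnings) and
#' `run.log` into the output directory.
#'
#' @param config an `ezpteRunConfig` from [runConfig()].
#' @return The output directory, invisibly; its `results` attribute holds
#'   the in-memory tables
#'   (`metrics`, `comparison`, `classification`, `pointAs`).
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "ezpteRunConfig"))
  outdir <- config$outdir
  if (is.null(outdir))
    outdir <- file.path(tempdir(), paste0("ezpte-run-",
                                          format(Sys.time(), "%H%M%S")))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logPath <- file.path(outdir, "run.log")
  warningsSeen <- character(0)
  logLine <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logPath,
                               append = TRUE)
  stage <- function(name, expr) {
    logLine("stage: ", name)
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ",
             conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warningsSeen <<- c(warningsSeen,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  dataIn <- stage("input", {
    if (!is.null(config$simulation)) {
      ds <- makeDataset(config$simulation)
      list(recording = ds$recording, zones = ds$zones,
           markers = ds$truth@markerTimes)
    } else {
      loadDataset(config$edfPath, config$zonesPath, config$markersPath)
    }
  })

  epochs <- stage("preprocess",
    preprocessRecording(dataIn$recording, dataIn$markers,
                        targetFs = config$targetFs, low = config$low,
                        high = config$high, notch = config$notch,
                        epochDuration = config$epochDuration))

  params <- pteParams(windowMs = config$windowMs, stepMs = config$stepMs)
  ana <- stage("network-analysis",
    analyzeEpochs(epochs, freqs = config$freqs, params = params,
                  thresholdQ = config$thresholdQ,
                  nCycles = config$nCycles))

  metrics <- stage("aggregate",
    aggregateMetrics(ana$perEpochMetrics, ana$perEpochPower,
                     zones = dataIn$zones))

  comparison <- stage("zone-statistics",
    compareZones(metrics, useCompensated = config$useCompensated))

  classification <- stage("classification", {
    params7 <- paste0(c("BC", "CC", "LE", "OD", "OS", "ID", "IS"),
                      if (config$useCompensated) "_comp" else "")
    logisticClassify(metrics[, params7], metrics$zone == "EZ")
  })

  stage("outputs", {
    utils::write.csv(metrics, file.path(outdir, "electrode_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(outdir, "comparison_table.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(channel = metrics$channel, zone = metrics$zone,
                 probability = classification$probabilities,
                 predictedEz = classification$predicted),
      file.path(outdir, "classification_report.csv"), row.names = FALSE)
    utils::write.csv(zoneBoxplotSummary(metrics, config$useCompensated),
                     file.path(outdir, "boxplot_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$pointAs, file.path(outdir, "point_a.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "ezpte",
      version = as.character(utils::packageVersion("ezpte")),
      rVersion = R.version.string,
      seed = config$seed,
      settings = config[c("targetFs", "low", "high", "notch", "windowMs",
                          "stepMs", "thresholdQ", "nCycles",
                          "epochDuration", "useCompensated")],
      freqs = config$freqs,
      simulation = if (!is.null(config$simulation)) list(
        nChannels = config$simulation@nChannels,
        zones = config$simulation@zones,
        nEpochs = config$simulation@nEpochs,
        iedKind = config$simulation@iedKind,
        snr = config$simulation@snr,
        burstFreq = config$simulation@burstFreq,
        couplingGainMz = config$simulation@couplingGainMz,
        couplingGainNz = config$simulation@couplingGainNz,
        lagMzMs = config$simulation@lagMzMs,
        lagNzMs = config$simulation@lagNzMs,
        seed = config$simulation@seed),
      classification = classification[c("accuracyEz", "accuracyOther",
                                        "separation")],
      warnings = warningsSeen)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  logLine("done")

  structure(invisible(outdir),
            results = list(metrics = metrics, comparison = comparison,
                           classification = classification,
                           pointAs = ana$pointAs))
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [runConfig()]; a `simulation`
#' mapping mirrors [simConfig()].
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file contents.
#' @return An `ezpteRunConfig`.
#' @export
runConfigFromYaml <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  sim <- NULL
  if (!is.null(y$simulation)) {
    simArgs <- y$simulation
    if (!is.null(simArgs$zones)) simArgs$zones <- unlist(simArgs$zones)
    sim <- do.call(simConfig, simArgs)
  } else if (is.null(y$edfPath)) {
    sim <- simConfig()
  }
  args <- y[setdiff(names(y), "simulation")]
  args$simulation <- sim
  if (!is.null(args$freqs)) args$freqs <- unlist(args$freqs)
  do.call(runConfig, args)
}
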