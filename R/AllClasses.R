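#' @import methods
#' @importFrom stats fft quantile rnorm runif median sd wilcox.test glm
#'   binomial predict coef var approx
#' @importFrom utils write.csv read.csv head tail
#' @useDynLib ezpte, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Central data containers. All are plain S4 with validity methods; signal
## data live in channel x sample (x epoch) arrays with channel labels as
## dimnames, mirroring the assay-matrix convention.
## ---------------------------------------------------------------------------

#' EcogRecording: a multichannel intracranial EEG recording
#'
#' Holds a channels-by-samples matrix of potentials (conventionally in
#' microvolts), its sampling rate, channel labels (rownames), the set of
#' channels flagged as bad, and the referencing state.
#'
#' @slot signals numeric matrix, channels x samples; rownames are channel
#'   labels.
#' @slot fs sampling rate in Hz.
#' @slot badChannels character vector of channel labels excluded from
#'   analysis (artifact channels).
#' @slot reference `"raw"` or `"common_average"`.
#'
#' @exportClass EcogRecording
setClass("EcogRecording",
  representation(
    signals = "matrix",
    fs = "numeric",
    badChannels = "character",
    reference = "character"
  ),
  prototype(badChannels = character(0), reference = "raw")
)

setValidity("EcogRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@signals)) msg <- c(msg, "signals must be numeric")
  if (is.null(rownames(object@signals)))
    msg <- c(msg, "signals must have channel labels as rownames")
  else if (anyDuplicated(rownames(object@signals)))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (any(!is.finite(object@signals)))
    msg <- c(msg, "signals contain NaN/Inf")
  if (!all(object@badChannels %in% rownames(object@signals)))
    msg <- c(msg, "badChannels must be a subset of channel labels")
  if (!object@reference %in% c("raw", "common_average"))
    msg <- c(msg, "reference must be 'raw' or 'common_average'")
  if (length(msg)) msg else TRUE
})

#' Construct an EcogRecording
#'
#' @param signals channels x samples numeric matrix. If it has no rownames,
#'   labels `ch01, ch02, ...` are attached.
#' @param fs sampling rate (Hz).
#' @param badChannels labels of artifact channels to exclude downstream.
#' @param reference referencing state of `signals`.
#' @return An [EcogRecording-class] object.
#' @export
EcogRecording <- function(signals, fs, badChannels = character(0),
                          reference = "raw") {
  signals <- as.matrix(signals)
  if (is.null(rownames(signals)))
    rownames(signals) <- sprintf("ch%02d", seq_len(nrow(signals)))
  new("EcogRecording", signals = signals, fs = fs,
      badChannels = as.character(badChannels), reference = reference)
}

#' EpochSet: IED-centered epochs cut from a recording
#'
#' @slot epochs numeric array, channels x samples x epochs; dimnames carry
#'   channel labels on the first margin.
#' @slot fs sampling rate in Hz (200 after rate standardization).
#' @slot epochDuration epoch length in seconds.
#' @slot markerIndex 1-based sample index of the IED marker inside each
#'   epoch (identical for all epochs: the marker is centered).
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    fs = "numeric",
    epochDuration = "numeric",
    markerIndex = "integer"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character(0)
  if (length(dim(object@epochs)) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (channels x samples x epochs)")
  else {
    if (any(!is.finite(object@epochs))) msg <- c(msg, "epochs contain NaN/Inf")
    ns <- dim(object@epochs)[2]
    if (abs(ns - object@epochDuration * object@fs) > 0.5)
      msg <- c(msg, "sample count inconsistent with epochDuration * fs")
    if (object@markerIndex < 1L || object@markerIndex > ns)
      msg <- c(msg, "markerIndex outside epoch")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname EpochSet-class
#' @param epochs channels x samples x epochs array.
#' @param fs sampling rate (Hz).
#' @param epochDuration epoch length (s).
#' @param markerIndex marker sample index within each epoch.
#' @export
EpochSet <- function(epochs, fs, epochDuration, markerIndex) {
  new("EpochSet", epochs = epochs, fs = fs, epochDuration = epochDuration,
      markerIndex = as.integer(markerIndex))
}

#' TFDecomposition: complex Morlet coefficients of one epoch
#'
#' @slot coefficients complex array, channels x frequencies x samples.
#' @slot freqs analysis frequencies (Hz), ascending.
#' @slot fs sampling rate (Hz).
#' @slot nCycles Morlet cycle count.
#' @slot edgeSamples integer vector per frequency: samples within one
#'   wavelet half-length of either epoch edge are unreliable.
#'
#' @exportClass TFDecomposition
setClass("TFDecomposition",
  representation(
    coefficients = "array",
    freqs = "numeric",
    fs = "numeric",
    nCycles = "numeric",
    edgeSamples = "integer"
  )
)

setValidity("TFDecomposition", function(object) {
  msg <- character(0)
  if (length(dim(object@coefficients)) != 3L)
    msg <- c(msg, "coefficients must be channels x freqs x samples")
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly ascending")
  if (length(object@edgeSamples) != length(object@freqs))
    msg <- c(msg, "edgeSamples must have one entry per frequency")
  if (length(msg)) msg else TRUE
})

#' TFMap: time-frequency synchrony map of one epoch
#'
#' Values are the mean pairwise phase transfer entropy per sliding window
#' and frequency, divided by the map maximum so the peak ("point A")
#' equals 1.
#'
#' @slot values numeric matrix, time (rows) x frequency (columns), in [0,1].
#' @slot times window-center times (s).
#' @slot freqs frequencies (Hz).
#' @slot pointA named numeric `c(time=, freq=)` of the map argmax.
#' @slot pointAIndex integer `c(timeIndex, freqIndex)` of the argmax.
#' @slot scale the pre-normalization map maximum (mean pairwise transfer
#'   entropy, bits); `values * scale` restores the raw map.
#'
#' @exportClass TFMap
setClass("TFMap",
  representation(
    values = "matrix",
    times = "numeric",
    freqs = "numeric",
    pointA = "numeric",
    pointAIndex = "integer",
    scale = "numeric"
  ),
  prototype(scale = 1)
)

setValidity("TFMap", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@times) ||
      ncol(object@values) != length(object@freqs))
    msg <- c(msg, "values dimensions must match times x freqs")
  if (length(object@pointAIndex) == 2L) {
    v <- object@values[object@pointAIndex[1], object@pointAIndex[2]]
    if (abs(v - max(object@values)) > 1e-12)
      msg <- c(msg, "pointA must be attained at the stored index")
  }
  if (length(msg)) msg else TRUE
})

#' PTEParams: parameters of the binned-phase transfer-entropy estimator
#'
#' @slot delay prediction lag in samples; `NA` means the quarter-cycle rule
#'   `max(1, round(fs / (4 f)))` at each analysis frequency.
#' @slot nBins phase-histogram bin count; `NA` means the occupancy
#'   heuristic `round(exp(0.626 + 0.4 log(n - delay - 1)))`.
#' @slot windowMs sliding/analysis window width (ms).
#' @slot stepMs sliding step (ms).
#' @slot normalize `"map_max"` (divide TF map by its max) or `"dPTE"`.
#'
#' @exportClass PTEParams
setClass("PTEParams",
  representation(
    delay = "numeric",
    nBins = "numeric",
    windowMs = "numeric",
    stepMs = "numeric",
    normalize = "character"
  ),
  prototype(delay = NA_real_, nBins = NA_real_, windowMs = 500,
            stepMs = 100, normalize = "map_max")
)

setValidity("PTEParams", function(object) {
  msg <- character(0)
  if (!is.na(object@delay) && object@delay < 1)
    msg <- c(msg, "delay must be >= 1 sample")
  if (!is.na(object@nBins) && object@nBins < 4)
    msg <- c(msg, "nBins must be >= 4")
  if (object@windowMs <= 0 || object@stepMs <= 0)
    msg <- c(msg, "window and step must be positive")
  if (!object@normalize %in% c("map_max", "dPTE"))
    msg <- c(msg, "normalize must be 'map_max' or 'dPTE'")
  if (length(msg)) msg else TRUE
})

#' @rdname PTEParams-class
#' @param delay,nBins,windowMs,stepMs,normalize see slots.
#' @export
pteParams <- function(delay = NA, nBins = NA, windowMs = 500, stepMs = 100,
                      normalize = "map_max") {
  new("PTEParams", delay = as.numeric(delay), nBins = as.numeric(nBins),
      windowMs = windowMs, stepMs = stepMs, normalize = normalize)
}

#' PTEAdjacency: directed PTE adjacency matrix with thresholded views
#'
#' `W[i, j]` is the phase transfer entropy from channel i to channel j at
#' the selected frequency within the analysis window. `Wthr` keeps only
#' entries strictly above the retention quantile of the off-diagonal
#' weights; `A` is its binary indicator.
#'
#' @slot W full nonnegative weight matrix, zero diagonal.
#' @slot Wthr thresholded weights.
#' @slot A binary adjacency (1 where Wthr > 0).
#' @slot thresholdQ removed-fraction quantile (default 0.70: lowest 70%
#'   of off-diagonal entries are removed).
#' @slot fStar analysis frequency (Hz).
#'
#' @exportClass PTEAdjacency
setClass("PTEAdjacency",
  representation(
    W = "matrix",
    Wthr = "matrix",
    A = "matrix",
    thresholdQ = "numeric",
    fStar = "numeric"
  )
)

setValidity("PTEAdjacency", function(object) {
  msg <- character(0)
  if (nrow(object@W) != ncol(object@W)) msg <- c(msg, "W must be square")
  if (any(diag(object@W) != 0)) msg <- c(msg, "W diagonal must be zero")
  if (any(object@W < 0)) msg <- c(msg, "W must be nonnegative")
  keepOk <- object@Wthr == 0 | abs(object@Wthr - object@W) < 1e-15
  if (!all(keepOk))
    msg <- c(msg, "Wthr entries must be 0 or the corresponding W entry")
  if (!all(object@A %in% c(0, 1))) msg <- c(msg, "A must be binary")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation containers
## ---------------------------------------------------------------------------

#' SimConfig: configuration of the synthetic ECoG generator
#'
#' Defaults describe a desk-scale montage: 16 channels (4 EZ / 4 MZ / 8 NZ),
#' 30 ten-second epochs at 200 Hz, spike-wave IEDs with a 21-Hz narrow-band
#' burst, EZ driving MZ strongly at short lag and NZ weakly at longer lag.
#'
#' @slot nChannels number of channels.
#' @slot zones character vector, one of `"EZ"`, `"MZ"`, `"NZ"` per channel.
#' @slot fs sampling rate (Hz).
#' @slot epochDuration epoch length (s).
#' @slot nEpochs number of IED events / epochs.
#' @slot iedKind `"spike_wave"` or `"polyspike_wave"`.
#' @slot couplingGainMz,couplingGainNz amplitude factors in [0, 1] applied
#'   to the composite received by MZ resp. NZ channels.
#' @slot lagMzMs,lagNzMs propagation lags (ms), EZ to MZ resp. NZ.
#' @slot burstFreq carrier frequency of the coupled narrow-band burst (Hz).
#' @slot noiseExponent spectral slope alpha of the 1/f^alpha background.
#' @slot snr EZ IED peak amplitude over background RMS.
#' @slot jitterSdMs SD of marker timing jitter (ms).
#' @slot seed RNG seed.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nChannels = "integer", zones = "character", fs = "numeric",
    epochDuration = "numeric", nEpochs = "integer", iedKind = "character",
    couplingGainMz = "numeric", couplingGainNz = "numeric",
    lagMzMs = "numeric", lagNzMs = "numeric", burstFreq = "numeric",
    noiseExponent = "numeric", snr = "numeric", jitterSdMs = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (length(object@zones) != object@nChannels)
    msg <- c(msg, "zones must assign every channel exactly once")
  if (!all(object@zones %in% c("EZ", "MZ", "NZ")))
    msg <- c(msg, "zones must be EZ, MZ or NZ")
  if (!all(c("EZ", "MZ", "NZ") %in% object@zones))
    msg <- c(msg, "at least one channel per zone is required")
  if (object@lagMzMs >= object@lagNzMs)
    msg <- c(msg, "lagMzMs must be < lagNzMs")
  if (object@couplingGainNz > object@couplingGainMz)
    msg <- c(msg, "couplingGainNz must be <= couplingGainMz")
  if (object@burstFreq < 3 || object@burstFreq > 65)
    msg <- c(msg, "burstFreq must lie in [3, 65] Hz")
  if (object@fs < 2 * 66.7)
    msg <- c(msg, "fs must be at least twice the band-pass high cutoff")
  if (any(!is.finite(c(object@couplingGainMz, object@couplingGainNz,
                       object@snr, object@noiseExponent))))
    msg <- c(msg, "non-finite simulation parameters")
  if (object@couplingGainMz < 0 || object@couplingGainMz > 1 ||
      object@couplingGainNz < 0 || object@couplingGainNz > 1)
    msg <- c(msg, "coupling gains must lie in [0, 1]")
  if (!object@iedKind %in% c("spike_wave", "polyspike_wave"))
    msg <- c(msg, "iedKind must be 'spike_wave' or 'polyspike_wave'")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nChannels,zones,fs,epochDuration,nEpochs,iedKind see slots.
#' @param couplingGainMz,couplingGainNz,lagMzMs,lagNzMs see slots.
#' @param burstFreq,noiseExponent,snr,jitterSdMs,seed see slots.
#' @export
simConfig <- function(nChannels = 16L,
                      zones = rep(c("EZ", "MZ", "NZ"), c(4, 4, 8)),
                      fs = 200, epochDuration = 10, nEpochs = 30L,
                      iedKind = "spike_wave",
                      couplingGainMz = 0.7, couplingGainNz = 0.1,
                      lagMzMs = 15, lagNzMs = 30, burstFreq = 21,
                      noiseExponent = 1, snr = 5, jitterSdMs = 20,
                      seed = 42L) {
  new("SimConfig", nChannels = as.integer(nChannels),
      zones = as.character(zones), fs = fs, epochDuration = epochDuration,
      nEpochs = as.integer(nEpochs), iedKind = iedKind,
      couplingGainMz = couplingGainMz, couplingGainNz = couplingGainNz,
      lagMzMs = lagMzMs, lagNzMs = lagNzMs, burstFreq = burstFreq,
      noiseExponent = noiseExponent, snr = snr, jitterSdMs = jitterSdMs,
      seed = as.integer(seed))
}

#' GroundTruth: what the generator actually injected
#'
#' @slot ezChannels,mzChannels,nzChannels channel indices per zone.
#' @slot markerTimes IED marker times (s), strictly increasing with
#'   inter-marker gap of at least one epoch duration.
#' @slot template the injected IED waveform (unit peak).
#' @slot coupling data.frame `from, to, gain, lagMs` of directed injected
#'   edges (EZ to MZ/NZ).
#' @slot droppedEvents number of events dropped at epoch boundaries.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    ezChannels = "integer", mzChannels = "integer", nzChannels = "integer",
    markerTimes = "numeric", template = "numeric", coupling = "data.frame",
    droppedEvents = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (length(object@markerTimes) > 1 &&
      any(diff(object@markerTimes) <= 0))
    msg <- c(msg, "markerTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "EcogRecording", function(object) {
  cat(sprintf("EcogRecording: %d channels x %d samples @ %g Hz (%s)\n",
              nrow(object@signals), ncol(object@signals), object@fs,
              object@reference))
  if (length(object@badChannels))
    cat("  bad channels:", paste(object@badChannels, collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "EpochSet: %d epochs x %d channels x %d samples @ %g Hz (marker at %d)\n",
    d[3], d[1], d[2], object@fs, object@markerIndex))
})

setMethod("show", "TFMap", function(object) {
  cat(sprintf("TFMap: %d windows x %d freqs; point A at t=%.2f s, f=%g Hz\n",
              nrow(object@values), ncol(object@values),
              object@pointA["time"], object@pointA["freq"]))
})

setMethod("show", "PTEAdjacency", function(object) {
  cat(sprintf(
    "PTEAdjacency: %d nodes, %d/%d edges retained (q=%.2f) at f*=%g Hz\n",
    nrow(object@W), sum(object@A), nrow(object@W) * (nrow(object@W) - 1),
    object@thresholdQ, object@fStar))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d channels (%d EZ/%d MZ/%d NZ), %d x %g-s epochs @ %g Hz, %s\n",
    object@nChannels, sum(object@zones == "EZ"), sum(object@zones == "MZ"),
    sum(object@zones == "NZ"), object@nEpochs, object@epochDuration,
    object@fs, object@iedKind))
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' Accessors for ezpte containers
#'
#' @param object an ezpte S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "EcogRecording",
          function(object) rownames(object@signals))
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet",
          function(object) dimnames(object@epochs)[[1]])

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EcogRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TFDecomposition", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setMethod("signalData", "EcogRecording", function(object) object@signals)

#' @rdname accessors
#' @export
setGeneric("goodChannels", function(object) standardGeneric("goodChannels"))
#' @rdname accessors
#' @export
setMethod("goodChannels", "EcogRecording", function(object)
  setdiff(rownames(object@signals), object@badChannels))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[3])

#' @rdname accessors
#' @param i epoch index.
#' @export
setGeneric("epochData", function(object, i) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(object, i)
  object@epochs[, , i, drop = TRUE])

#' @rdname accessors
#' @export
setGeneric("pointA", function(object) standardGeneric("pointA"))
#' @rdname accessors
#' @export
setMethod("pointA", "TFMap", function(object) object@pointA)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "TFMap", function(object) {
  v <- object@values
  dimnames(v) <- list(time = sprintf("%.3f", object@times),
                      freq = sprintf("%g", object@freqs))
  v
})

#' @rdname accessors
#' @export
setGeneric("adjacencyWeights", function(object)
  standardGeneric("adjacencyWeights"))
#' @rdname accessors
#' @export
setMethod("adjacencyWeights", "PTEAdjacency", function(object) object@W)

#' @rdname accessors
#' @export
setGeneric("thresholdedWeights", function(object)
  standardGeneric("thresholdedWeights"))
#' @rdname accessors
#' @export
setMethod("thresholdedWeights", "PTEAdjacency", function(object) object@Wthr)

#' @rdname accessors
#' @export
setGeneric("binaryAdjacency", function(object)
  standardGeneric("binaryAdjacency"))
#' @rdname accessors
#' @export
setMethod("binaryAdjacency", "PTEAdjacency", function(object) object@A)
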