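## Synthetic ECoG with known epileptogenic coupling.
##
## Background is 1/f^alpha colored noise, independent per channel, unit
## variance. At each IED marker a composite event -- a spike(-wave) template
## plus a 500-ms narrow-band burst -- is injected: epileptogenic-zone (EZ)
## channels receive it at full amplitude, margin-zone (MZ) channels a strong
## short-lag copy, normal-zone (NZ) channels a weak long-lag copy. The burst
## is stochastic (band-passed Gaussian noise), so its phase carries
## information that directed phase-coupling estimators can detect; a
## deterministic sinusoid would leave no residual uncertainty about the
## target's future once its own past is known.

#' Generate 1/f^alpha background noise
#'
#' Each channel is an independent realization of colored noise whose power
#' spectral density falls off as 1/f^alpha, synthesized by FFT spectral
#' shaping of white Gaussian noise (DC removed), then standardized to zero
#' mean and unit variance.
#'
#' @param nChannels number of channels.
#' @param nSamples samples per channel.
#' @param fs sampling rate (Hz).
#' @param noiseExponent spectral slope alpha (>= 0); 0 gives white noise.
#' @param seed RNG seed (NULL to use the current RNG state).
#' @return An [EcogRecording-class] with unit-variance channels.
#' @export
generateBackground <- function(nChannels, nSamples, fs, noiseExponent = 1,
                               seed = NULL) {
  if (!is.finite(nSamples) || nSamples <= 0) stop("nSamples must be positive")
  if (!is.finite(noiseExponent) || noiseExponent < 0)
    stop("noiseExponent must be finite and >= 0")
  if (!is.finite(fs) || fs <= 0) stop("fs must be finite and positive")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nSamples)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # two-sided frequency index, |f|
  shape <- c(0, (f[-1] * fs / n)^(-noiseExponent / 2))  # kill DC
  x <- matrix(0, nrow = nChannels, ncol = n)
  for (ch in seq_len(nChannels)) {
    w <- stats::rnorm(n)
    s <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    x[ch, ] <- (s - mean(s)) / stats::sd(s)
  }
  EcogRecording(x, fs = fs)
}

#' Construct an interictal-discharge waveform template
#'
#' A minimal parameterization of the two morphologies used: one (spike-wave)
#' or several (polyspike-wave) biphasic sharp transients followed by a slow
#' half-sine wave. The waveform is demeaned and normalized to unit peak
#' absolute amplitude.
#'
#' @param iedKind `"spike_wave"` or `"polyspike_wave"`.
#' @param fs sampling rate (Hz).
#' @param spikeWidthMs width of one biphasic spike (ms).
#' @param slowWaveMs duration of the slow wave (ms); must exceed
#'   `spikeWidthMs`.
#' @param nSpikes number of spikes: 1 for spike_wave, >= 2 for
#'   polyspike_wave (defaults 1 and 3).
#' @return Numeric waveform vector, `max(abs(.)) == 1`, mean 0.
#' @export
makeIedTemplate <- function(iedKind = c("spike_wave", "polyspike_wave"),
                            fs = 200, spikeWidthMs = 70, slowWaveMs = 300,
                            nSpikes = NULL) {
  iedKind <- match.arg(iedKind)
  if (spikeWidthMs >= slowWaveMs)
    stop("spikeWidthMs must be smaller than slowWaveMs")
  if (is.null(nSpikes)) nSpikes <- if (iedKind == "spike_wave") 1L else 3L
  if (iedKind == "spike_wave" && nSpikes != 1L)
    stop("spike_wave requires nSpikes = 1")
  if (iedKind == "polyspike_wave" && nSpikes < 2L)
    stop("polyspike_wave requires nSpikes >= 2")

  wSpike <- max(4L, round(spikeWidthMs / 1000 * fs))
  wSlow <- max(8L, round(slowWaveMs / 1000 * fs))
  ## biphasic spike: one full sine period (positive lobe then negative lobe)
  spike <- sin(2 * pi * seq(0, wSpike - 1) / wSpike)
  spikes <- rep(spike, nSpikes)
  slow <- 0.5 * sin(pi * seq(0, wSlow - 1) / (wSlow - 1))
  w <- c(spikes, slow)
  w <- w - mean(w)
  w / max(abs(w))
}

#' Narrow-band Gaussian noise burst
#'
#' Band-passed (FFT mask of `bandwidth` Hz around `centerFreq`) white
#' Gaussian noise, optionally Hann-windowed, normalized to unit RMS. This
#' is the stochastic oscillatory component co-injected with each IED: its
#' phase carries information, which is what directed phase-coupling
#' estimators need (a deterministic sinusoid's future is fully predicted
#' by its own past).
#'
#' @param nSamples burst length in samples.
#' @param fs sampling rate (Hz).
#' @param centerFreq carrier frequency (Hz).
#' @param bandwidth pass-band width (Hz), default 4.
#' @param hann apply a Hann taper (default TRUE; use FALSE for a
#'   stationary narrow-band series).
#' @return Numeric vector of length `nSamples`, unit RMS.
#' @export
narrowbandBurst <- function(nSamples, fs, centerFreq, bandwidth = 4,
                            hann = TRUE) {
  n <- as.integer(nSamples)
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  keep <- abs(f - centerFreq) <= bandwidth / 2
  if (!any(keep)) keep <- abs(f - centerFreq) == min(abs(f - centerFreq))
  b <- Re(stats::fft(stats::fft(w) * keep, inverse = TRUE)) / n
  if (hann) b <- b * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  b / sqrt(mean(b^2))
}

#' Inject IED events with known EZ/MZ/NZ coupling into a background
#'
#' At each marker the composite event (template plus 500-ms narrow-band
#' burst centered on the spike) is added to all EZ channels; MZ channels
#' receive it scaled by `couplingGainMz` and delayed by `lagMzMs`; NZ
#' channels scaled by `couplingGainNz` (0 allowed) and delayed by `lagNzMs`.
#' The event is scaled so that the EZ-channel peak over the background RMS
#' (which is 1 by construction) equals `snr`. Events whose lagged extent
#' would cross their epoch boundary are dropped with a warning.
#'
#' @param background an [EcogRecording-class] from [generateBackground()].
#' @param config a [SimConfig-class].
#' @return `list(recording =, truth =)` with the modified recording and a
#'   [GroundTruth-class].
#' @export
injectIeds <- function(background, config) {
  stopifnot(is(background, "EcogRecording"), is(config, "SimConfig"))
  x <- signalData(background)
  fs <- samplingRate(background)
  nSamp <- ncol(x)
  epochSamp <- round(config@epochDuration * fs)
  guard <- max(0.2, 12 * config@jitterSdMs / 1000)
  slot <- config@epochDuration + guard
  need <- ceiling(config@nEpochs * slot + guard) * fs
  if (nSamp < need)
    stop("background too short: need at least ", need, " samples for ",
         config@nEpochs, " non-overlapping epochs")

  set.seed(config@seed + 1L)
  jit <- stats::rnorm(config@nEpochs, 0, config@jitterSdMs / 1000)
  jit <- pmin(pmax(jit, -guard / 2), guard / 2)
  markerTimes <- guard / 2 + (seq_len(config@nEpochs) - 0.5) * slot + jit

  template <- makeIedTemplate(config@iedKind, fs = fs)
  pk <- which.max(template)
  Lb <- round(0.5 * fs)
  halfB <- Lb %/% 2

  zones <- config@zones
  ez <- which(zones == "EZ"); mz <- which(zones == "MZ")
  nz <- which(zones == "NZ")
  lagMz <- round(config@lagMzMs / 1000 * fs)
  lagNz <- round(config@lagNzMs / 1000 * fs)

  dropped <- 0L
  keptTimes <- numeric(0)
  for (k in seq_len(config@nEpochs)) {
    m0 <- round(markerTimes[k] * fs)              # marker sample (1-based-ish)
    burst <- 0.5 * narrowbandBurst(Lb, fs, config@burstFreq)
    ## assemble event with the marker at index M0: spike peak and burst
    ## center both sit on the marker
    M0 <- max(pk, halfB + 1L)
    Le <- M0 + max(length(template) - pk, Lb - halfB - 1L)
    ev <- numeric(Le)
    ti <- (M0 - pk + 1):(M0 - pk + length(template))
    ev[ti] <- ev[ti] + template
    bi <- (M0 - halfB):(M0 - halfB + Lb - 1L)
    ev[bi] <- ev[bi] + burst
    ev <- ev * config@snr / max(abs(ev))

    s0 <- m0 - M0 + 1L
    epochLo <- m0 - epochSamp %/% 2 + 1L
    epochHi <- m0 + epochSamp %/% 2
    maxLag <- max(lagMz, if (length(nz)) lagNz else 0L)
    if (s0 < max(1L, epochLo) ||
        s0 + Le - 1L + maxLag > min(nSamp, epochHi)) {
      dropped <- dropped + 1L
      next
    }
    idx <- s0:(s0 + Le - 1L)
    for (ch in ez) x[ch, idx] <- x[ch, idx] + ev
    if (config@couplingGainMz > 0)
      for (ch in mz)
        x[ch, idx + lagMz] <- x[ch, idx + lagMz] + config@couplingGainMz * ev
    if (config@couplingGainNz > 0)
      for (ch in nz)
        x[ch, idx + lagNz] <- x[ch, idx + lagNz] + config@couplingGainNz * ev
    keptTimes <- c(keptTimes, m0 / fs)
  }
  if (dropped > 0L)
    warning(dropped, " event(s) dropped at epoch boundaries")

  coupling <- rbind(
    expand.grid(from = ez, to = mz),
    expand.grid(from = ez, to = nz)
  )
  coupling$gain <- rep(c(config@couplingGainMz, config@couplingGainNz),
                       c(length(ez) * length(mz), length(ez) * length(nz)))
  coupling$lagMs <- rep(c(config@lagMzMs, config@lagNzMs),
                        c(length(ez) * length(mz), length(ez) * length(nz)))

  truth <- new("GroundTruth", ezChannels = as.integer(ez),
               mzChannels = as.integer(mz), nzChannels = as.integer(nz),
               markerTimes = keptTimes, template = template,
               coupling = coupling, droppedEvents = dropped)
  list(recording = EcogRecording(x, fs = fs), truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Composes [generateBackground()] and [injectIeds()]; optionally writes the
#' recording as EDF with side-car CSVs (`channel,zone` labels and
#' `marker_seconds` events); returns the in-memory epochs and ground truth.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory for `recording.edf`, `zones.csv`,
#'   `markers.csv`; `NULL` keeps everything in memory.
#' @return `list(recording, epochs, truth, zones, paths)` where `epochs` is
#'   an [EpochSet-class] of raw (unfiltered) marker-centered epochs.
#' @export
makeDataset <- function(config = simConfig(), dir = NULL) {
  stopifnot(is(config, "SimConfig"))
  guard <- max(0.2, 12 * config@jitterSdMs / 1000)
  nSamples <- ceiling(config@nEpochs * (config@epochDuration + guard) +
                        guard) * config@fs
  bg <- generateBackground(config@nChannels, nSamples, config@fs,
                           config@noiseExponent, seed = config@seed)
  sim <- injectIeds(bg, config)
  epochs <- extractEpochs(sim$recording, sim$truth@markerTimes,
                          duration = config@epochDuration)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir))
      dir.create(dir, recursive = TRUE)
    paths <- list(edf = file.path(dir, "recording.edf"),
                  zones = file.path(dir, "zones.csv"),
                  markers = file.path(dir, "markers.csv"))
    writeEdf(sim$recording, paths$edf)
    utils::write.csv(
      data.frame(channel = channelLabels(sim$recording),
                 zone = config@zones),
      paths$zones, row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(marker_seconds = sim$truth@markerTimes),
                     paths$markers, row.names = FALSE, quote = FALSE)
  }
  list(recording = sim$recording, epochs = epochs, truth = sim$truth,
       zones = config@zones, paths = paths)
}
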