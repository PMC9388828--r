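## Complex Morlet decomposition: instantaneous phase and power per channel
## and narrow-band frequency. Fixed-cycle wavelets (default 7 cycles)
## convolved by FFT; the kernel is L1-normalized (times 2) so a unit cosine
## returns coefficients of magnitude ~1 at its own frequency.

#' Complex Morlet time-frequency decomposition of one epoch
#'
#' @param epoch channels x samples numeric matrix (one epoch), or an
#'   [EpochSet-class] together with `i`.
#' @param fs sampling rate (Hz); taken from the EpochSet when one is given.
#' @param freqs analysis frequencies (Hz), default `seq(3, 65, by = 2)`.
#' @param nCycles Morlet cycle count (>= 3), default 7.
#' @param i epoch index when `epoch` is an [EpochSet-class].
#' @return A [TFDecomposition-class]; `edgeSamples` flags how many samples
#'   at each edge lie within one wavelet half-length per frequency.
#' @export
morletDecompose <- function(epoch, fs = NULL, freqs = seq(3, 65, by = 2),
                            nCycles = 7, i = 1L) {
  if (is(epoch, "EpochSet")) {
    fs <- samplingRate(epoch)
    epoch <- epochData(epoch, i)
  }
  if (is.null(fs)) stop("fs is required for a plain matrix epoch")
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be ascending")
  if (min(freqs) < 3 - 1e-9) stop("frequencies below 3 Hz are not supported")
  if (max(freqs) > fs / 3 + 1e-9)
    stop("max frequency must not exceed fs/3 (anti-aliasing rule)")
  if (nCycles < 3) stop("nCycles must be >= 3")

  nc <- nrow(epoch); ns <- ncol(epoch)
  ## longest wavelet (lowest frequency) must fit the epoch
  sigmaMax <- nCycles / (2 * pi * min(freqs))
  halfMax <- ceiling(3.5 * sigmaMax * fs)
  if (2 * halfMax + 1 > ns)
    stop("epoch shorter than the longest wavelet (", 2 * halfMax + 1,
         " samples needed)")

  nfft <- stats::nextn(ns + 2 * halfMax + 1, 2)
  Xf <- matrix(0 + 0i, nrow = nc, ncol = nfft)
  for (ch in seq_len(nc))
    Xf[ch, ] <- stats::fft(c(epoch[ch, ], numeric(nfft - ns)))

  coef <- array(0 + 0i, dim = c(nc, length(freqs), ns),
                dimnames = list(rownames(epoch), NULL, NULL))
  edge <- integer(length(freqs))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- nCycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma * fs)
    tt <- seq(-half, half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma^2))
    w <- 2 * w / sum(Mod(w))
    Wf <- stats::fft(c(w, numeric(nfft - length(w))))
    for (ch in seq_len(nc)) {
      conv <- stats::fft(Xf[ch, ] * Wf, inverse = TRUE) / nfft
      coef[ch, fi, ] <- conv[(half + 1):(half + ns)]
    }
    edge[fi] <- as.integer(half)
  }
  new("TFDecomposition", coefficients = coef, freqs = freqs, fs = fs,
      nCycles = nCycles, edgeSamples = edge)
}

.freqIndex <- function(tfd, freq) {
  fi <- match(freq, tfd@freqs)
  if (is.na(fi))
    stop("frequency ", freq, " Hz is not in the decomposition")
  fi
}

#' Instantaneous phase at one channel and frequency
#'
#' @param tfd a [TFDecomposition-class].
#' @param channel channel index or label.
#' @param freq frequency (Hz); must be one of the decomposed frequencies.
#' @return Phase series in (-pi, pi].
#' @export
instantaneousPhase <- function(tfd, channel, freq) {
  stopifnot(is(tfd, "TFDecomposition"))
  Arg(tfd@coefficients[channel, .freqIndex(tfd, freq), ])
}

#' Instantaneous power at one channel and frequency
#'
#' @inheritParams instantaneousPhase
#' @return Squared-magnitude power series.
#' @export
instantaneousPower <- function(tfd, channel, freq) {
  stopifnot(is(tfd, "TFDecomposition"))
  Mod(tfd@coefficients[channel, .freqIndex(tfd, freq), ])^2
}

## all-channel phase matrix (samples x channels) at one frequency index
.phaseMatrix <- function(tfd, fi) {
  t(Arg(tfd@coefficients[, fi, , drop = TRUE]))
}
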