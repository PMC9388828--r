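## Signal conditioning: bad-channel removal -> common average reference ->
## rate standardization (200 Hz) -> zero-phase FIR band-pass (0.5-66.7 Hz)
## -> 60 Hz notch -> marker-centered epoching. Filtering is forward-backward
## (filtfilt) over symmetric FIR kernels, so the net phase response is zero
## and pulse peaks do not move.

#' Drop bad channels from a recording
#'
#' @param recording an [EcogRecording-class].
#' @return The recording restricted to good channels.
#' @export
dropBadChannels <- function(recording) {
  stopifnot(is(recording, "EcogRecording"))
  good <- goodChannels(recording)
  if (length(good) == 0) stop("no good channels remain")
  EcogRecording(signalData(recording)[good, , drop = FALSE],
                fs = samplingRate(recording),
                reference = recording@reference)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across good channels from every good
#' channel; bad channels are dropped first. After referencing the
#' cross-channel mean is zero at every sample, and the operation is
#' idempotent.
#'
#' @param recording an [EcogRecording-class] with at least two good
#'   channels.
#' @return A re-referenced [EcogRecording-class].
#' @export
commonAverageReference <- function(recording) {
  stopifnot(is(recording, "EcogRecording"))
  recording <- dropBadChannels(recording)
  x <- signalData(recording)
  if (nrow(x) < 2)
    stop("common average reference requires at least 2 good channels")
  x <- sweep(x, 2, colMeans(x))
  EcogRecording(x, fs = samplingRate(recording),
                reference = "common_average")
}

## zero-phase low-pass; order is capped so filtfilt has room to operate
.zeroPhaseLowpass <- function(x, fs, cutoff, order = 240) {
  order <- min(order, 2 * (floor((ncol(x) - 1) / 6)))
  order <- max(order - order %% 2, 8)          # even order, linear phase
  h <- signal::fir1(order, cutoff / (fs / 2), type = "low")
  t(apply(x, 1, function(ch) signal::filtfilt(h, ch)))
}

#' Standardize the sampling rate
#'
#' Anti-alias low-pass (zero-phase FIR at 80% of the target Nyquist) then
#' decimation to exactly `targetFs`. Integer decimation factors are taken
#' directly; rational factors are handled by linear interpolation of the
#' anti-aliased signal onto the new sample grid. Upsampling is refused.
#'
#' @param recording an [EcogRecording-class] with `fs >= targetFs`.
#' @param targetFs target rate (Hz), default 200.
#' @return The recording at `targetFs`; pass-through if already there.
#' @export
standardizeRate <- function(recording, targetFs = 200) {
  stopifnot(is(recording, "EcogRecording"))
  fs <- samplingRate(recording)
  if (fs < targetFs) stop("refusing to upsample: fs < targetFs")
  if (abs(fs - targetFs) < 1e-9) return(recording)
  x <- signalData(recording)
  xf <- .zeroPhaseLowpass(x, fs, cutoff = 0.8 * targetFs / 2)
  rownames(xf) <- rownames(x)
  ratio <- fs / targetFs
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(xf), by = round(ratio))
    y <- xf[, idx, drop = FALSE]
  } else {
    tOld <- (seq_len(ncol(xf)) - 1) / fs
    tNew <- seq(0, tOld[length(tOld)], by = 1 / targetFs)
    y <- t(apply(xf, 1, function(ch)
      stats::approx(tOld, ch, xout = tNew)$y))
    rownames(y) <- rownames(x)
  }
  EcogRecording(y, fs = targetFs, reference = recording@reference)
}

#' Zero-phase band-pass and notch filtering
#'
#' FIR band-pass between `low` and `high` Hz followed by an FIR band-stop
#' notch, both applied forward-backward so the phase response is exactly
#' zero (symmetric pulse peaks are not displaced). The high cutoff defaults
#' to one-third of the 200-Hz standardized rate; the notch to the 60-Hz
#' mains frequency.
#'
#' @param recording an [EcogRecording-class].
#' @param low,high band-pass cutoffs (Hz).
#' @param notch notch center frequency (Hz); `NA` disables the notch.
#' @param notchHalfWidthHz half-width of the stop band (Hz).
#' @return The filtered [EcogRecording-class].
#' @export
bandpassNotch <- function(recording, low = 0.5, high = 66.7, notch = 60,
                          notchHalfWidthHz = 2) {
  stopifnot(is(recording, "EcogRecording"))
  fs <- samplingRate(recording)
  if (low >= high) stop("invalid band: low must be < high")
  if (high >= fs / 2) stop("high cutoff must be below Nyquist")
  if (!is.na(notch) && (notch <= low || notch >= high))
    stop("notch must lie inside the pass band")
  x <- signalData(recording)
  n <- ncol(x)

  ## band-pass: order sized for a ~1 Hz transition at the low edge,
  ## capped so filtfilt's edge padding fits the data
  ordBp <- min(round(3.3 * fs / 1), 2 * floor((n - 1) / 6))
  ordBp <- max(ordBp - ordBp %% 2, 8)
  hBp <- signal::fir1(ordBp, c(low, high) / (fs / 2), type = "pass")
  ## notch: ~2 Hz-wide stop band
  hNo <- NULL
  if (!is.na(notch)) {
    ordNo <- min(round(3.3 * fs / 1), 2 * floor((n - 1) / 6))
    ordNo <- max(ordNo - ordNo %% 2, 8)
    hNo <- signal::fir1(ordNo,
                        c(notch - notchHalfWidthHz, notch + notchHalfWidthHz) /
                          (fs / 2), type = "stop")
  }
  y <- t(apply(x, 1, function(ch) {
    ch <- ch - mean(ch)            # explicit DC removal; the FIR high-pass
                                   # edge then only has to handle drift
    ch <- signal::filtfilt(hBp, ch)
    if (!is.null(hNo)) ch <- signal::filtfilt(hNo, ch)
    ch
  }))
  rownames(y) <- rownames(x)
  EcogRecording(y, fs = fs, reference = recording@reference)
}

#' Extract marker-centered epochs
#'
#' One epoch per marker, the marker sample at the epoch center. Markers
#' whose window does not fit inside the recording are skipped with a
#' warning.
#'
#' @param recording an [EcogRecording-class].
#' @param markers marker times (s).
#' @param duration epoch length (s), default 10.
#' @return An [EpochSet-class].
#' @export
extractEpochs <- function(recording, markers, duration = 10) {
  stopifnot(is(recording, "EcogRecording"))
  x <- signalData(recording)
  fs <- samplingRate(recording)
  nSamp <- ncol(x)
  epochSamp <- round(duration * fs)
  half <- epochSamp %/% 2

  starts <- integer(0)
  skipped <- 0L
  for (m in markers) {
    c0 <- round(m * fs)
    lo <- c0 - half                 # epoch = [c0 - half, c0 + half - 1]
    ## require a full symmetric margin: an epoch that only just grazes the
    ## recording edge is treated as an edge case and rejected
    if (lo < 1L || c0 + half > nSamp) skipped <- skipped + 1L else
      starts <- c(starts, lo)
  }
  if (skipped > 0L)
    warning(skipped, " marker(s) too close to the recording edge, skipped")
  if (length(starts) == 0L) stop("no valid markers: nothing to epoch")

  ep <- array(0, dim = c(nrow(x), epochSamp, length(starts)),
              dimnames = list(rownames(x), NULL, NULL))
  for (k in seq_along(starts))
    ep[, , k] <- x[, starts[k]:(starts[k] + epochSamp - 1L)]
  EpochSet(ep, fs = fs, epochDuration = duration,
           markerIndex = half + 1L)
}

#' Run the full preprocessing chain
#'
#' Fixed order: bad-channel removal, common average reference, rate
#' standardization to 200 Hz, band-pass, notch, epoching.
#'
#' @param recording an [EcogRecording-class].
#' @param markers IED marker times (s).
#' @param targetFs standardized rate (Hz).
#' @param low,high,notch filter settings, see [bandpassNotch()].
#' @param epochDuration epoch length (s).
#' @return An [EpochSet-class] of conditioned epochs.
#' @export
preprocessRecording <- function(recording, markers, targetFs = 200,
                                low = 0.5, high = 66.7, notch = 60,
                                epochDuration = 10) {
  recording <- commonAverageReference(recording)   # drops bad channels
  recording <- standardizeRate(recording, targetFs)
  recording <- bandpassNotch(recording, low, high, notch)
  extractEpochs(recording, markers, epochDuration)
}
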