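## Binned-phase transfer entropy (PTE), its directional normalization
## (dPTE), the sliding time-frequency synchrony map, and point-A selection.
##
## The estimator is the plug-in (histogram) transfer entropy on
## uniform-width phase bins over (-pi, pi]:
##   TE(X -> Y) = sum p(y_{t+d}, y_t, x_t) log2[ p(y_{t+d}|y_t, x_t)
##                                               / p(y_{t+d}|y_t) ]
## in bits. The prediction lag d defaults to a quarter cycle of the
## analysis frequency; the bin count to an occupancy heuristic in the
## effective sample count.

#' Quarter-cycle prediction lag (samples)
#'
#' @param fs sampling rate (Hz).
#' @param freq analysis frequency (Hz).
#' @return `max(1, round(fs / (4 * freq)))`.
#' @export
pteDelay <- function(fs, freq) max(1L, as.integer(round(fs / (4 * freq))))

#' Histogram bin-count heuristic for phase transfer entropy
#'
#' `round(exp(0.626 + 0.4 log(n - delay - 1)))`, capped at `n / 10` so
#' that each phase bin can hold at least ten window samples (minimum
#' occupancy).
#'
#' @param n window sample count.
#' @param delay prediction lag (samples).
#' @return Integer bin count (>= 4).
#' @export
pteNBins <- function(n, delay) {
  eff <- n - delay - 1
  if (eff < 4) stop("window too short for the requested delay")
  b <- round(exp(0.626 + 0.4 * log(eff)))
  max(4L, as.integer(min(b, floor(n / 10))))
}

#' Bin instantaneous phases into integer symbols
#'
#' Uniform-width, right-closed bins over (-pi, pi].
#'
#' @param phases numeric vector or matrix of phases in (-pi, pi].
#' @param nBins number of bins (>= 2).
#' @return Integer symbols in `[0, nBins)`, same shape as `phases`.
#' @export
binPhases <- function(phases, nBins) {
  if (length(phases) == 0) stop("empty phase series")
  if (any(!is.finite(phases))) stop("phases must be finite")
  if (any(phases <= -pi - 1e-9 | phases > pi + 1e-9))
    stop("phases must lie in (-pi, pi]")
  ## right-closed bins: symbol k covers (-pi + k*w, -pi + (k+1)*w]
  w <- 2 * pi / nBins
  s <- as.integer(ceiling((phases + pi) / w) - 1L)
  s[s < 0L] <- 0L
  s[s >= nBins] <- nBins - 1L
  if (is.matrix(phases)) s <- matrix(s, nrow = nrow(phases))
  s
}

#' Plug-in transfer entropy between two symbol sequences
#'
#' @param xSym,ySym equal-length integer symbol sequences (source,
#'   target), e.g. from [binPhases()].
#' @param delay prediction lag in samples (>= 1, < sequence length).
#' @param nBins symbol alphabet size; defaults to `max(symbols) + 1`.
#' @return TE(X -> Y) in bits (nonnegative).
#' @export
transferEntropy <- function(xSym, ySym, delay, nBins = NULL) {
  if (length(xSym) != length(ySym)) stop("sequences must have equal length")
  if (delay >= length(xSym)) stop("delay must be shorter than the sequences")
  if (is.null(nBins)) nBins <- max(xSym, ySym) + 1L
  sym <- cbind(as.integer(xSym), as.integer(ySym))
  pteMatrixCpp(sym, as.integer(delay), as.integer(nBins))[1, 2]
}

#' Pairwise phase transfer entropy and its directional index
#'
#' @param phaseX,phaseY phase series in (-pi, pi].
#' @param params a [PTEParams-class]; `NA` delay/bins fall back to the
#'   quarter-cycle and occupancy rules via `fs` and `freq`.
#' @param fs,freq sampling rate and analysis frequency (Hz), used only to
#'   resolve `NA` parameters.
#' @return `list(pteXY, pteYX, dpteXY)` with
#'   `dpteXY = pteXY / (pteXY + pteYX)` in [0, 1], defined as 0.5 when
#'   both directions are zero.
#' @export
ptePair <- function(phaseX, phaseY, params = pteParams(), fs = NULL,
                    freq = NULL) {
  stopifnot(is(params, "PTEParams"))
  n <- length(phaseX)
  delay <- params@delay
  if (is.na(delay)) {
    if (is.null(fs) || is.null(freq))
      stop("fs and freq are required when delay is NA")
    delay <- pteDelay(fs, freq)
  }
  nBins <- params@nBins
  if (is.na(nBins)) nBins <- pteNBins(n, delay)
  sym <- cbind(binPhases(phaseX, nBins), binPhases(phaseY, nBins))
  te <- pteMatrixCpp(sym, as.integer(delay), as.integer(nBins))
  pteXY <- te[1, 2]; pteYX <- te[2, 1]
  dpte <- if (pteXY + pteYX == 0) 0.5 else pteXY / (pteXY + pteYX)
  list(pteXY = pteXY, pteYX = pteYX, dpteXY = dpte)
}

## sliding-window center samples (1-based) such that the full window fits
.windowCenters <- function(nSamples, fs, windowMs, stepMs) {
  winSamp <- round(windowMs / 1000 * fs)
  half <- winSamp %/% 2
  stepSamp <- max(1L, round(stepMs / 1000 * fs))
  seq(half + 1L, nSamples - (winSamp - half) + 1L, by = stepSamp)
}

#' Time-frequency phase-synchrony map of one epoch and point-A selection
#'
#' For every sliding-window center and analysis frequency, the mean
#' pairwise transfer entropy over all ordered channel pairs is computed
#' from binned instantaneous phases. The map is divided by its maximum so
#' the peak equals 1, and point A is the argmax (ties broken toward the
#' earliest time, then the lowest frequency). Window centers are restricted
#' so that the full window fits inside the epoch.
#'
#' @param tfd a [TFDecomposition-class] of the epoch (all channels).
#' @param params a [PTEParams-class].
#' @return A [TFMap-class].
#' @export
tfSynchronyMap <- function(tfd, params = pteParams()) {
  stopifnot(is(tfd, "TFDecomposition"), is(params, "PTEParams"))
  nc <- dim(tfd@coefficients)[1]
  if (nc < 2) stop("synchrony map requires at least 2 channels")
  ns <- dim(tfd@coefficients)[3]
  fs <- tfd@fs
  winSamp <- round(params@windowMs / 1000 * fs)
  half <- winSamp %/% 2
  centers <- .windowCenters(ns, fs, params@windowMs, params@stepMs)
  if (length(centers) == 0) stop("window does not fit inside the epoch")

  values <- matrix(0, nrow = length(centers), ncol = length(tfd@freqs))
  offDiag <- nc * (nc - 1)
  for (fi in seq_along(tfd@freqs)) {
    f <- tfd@freqs[fi]
    delay <- if (is.na(params@delay)) pteDelay(fs, f) else
      as.integer(params@delay)
    nBins <- if (is.na(params@nBins)) pteNBins(winSamp, delay) else
      as.integer(params@nBins)
    ph <- .phaseMatrix(tfd, fi)                  # samples x channels
    sym <- binPhases(ph, nBins)
    for (wi in seq_along(centers)) {
      idx <- (centers[wi] - half):(centers[wi] - half + winSamp - 1L)
      te <- pteMatrixCpp(sym[idx, , drop = FALSE], delay, nBins)
      values[wi, fi] <- sum(te) / offDiag
    }
  }

  mx <- max(values)
  if (mx <= 0) stop("all-zero synchrony map: point A is undefined")
  values <- values / mx
  hits <- which(values == max(values), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  ti <- hits[1, 1]; fi <- hits[1, 2]
  times <- (centers - 1) / fs
  new("TFMap", values = values, times = times, freqs = tfd@freqs,
      pointA = c(time = times[ti], freq = tfd@freqs[fi]),
      pointAIndex = c(ti, fi), scale = mx)
}

#' Analysis-window sample range centered on point A
#'
#' Half-open interval of `windowMs` worth of samples centered on the
#' point-A time; returned as 1-based sample indices. Window centers are
#' already restricted during selection so the window always fits.
#'
#' @param pointATime point-A time (s).
#' @param fs sampling rate (Hz).
#' @param windowMs window width (ms), default 500.
#' @param nSamples epoch length in samples (for the fit check).
#' @return Integer vector of sample indices (length `windowMs * fs / 1000`).
#' @export
analysisWindow <- function(pointATime, fs, windowMs = 500, nSamples = NULL) {
  winSamp <- round(windowMs / 1000 * fs)
  half <- winSamp %/% 2
  center <- round(pointATime * fs) + 1L           # 1-based center sample
  idx <- (center - half):(center + winSamp - half - 1L)
  if (idx[1] < 1L || (!is.null(nSamples) && idx[winSamp] > nSamples))
    stop("analysis window does not fit inside the epoch")
  idx
}

#' Export a TF map as a CSV matrix (rows = time, columns = frequency)
#'
#' @param tfmap a [TFMap-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTFMapCsv <- function(tfmap, path) {
  stopifnot(is(tfmap, "TFMap"))
  m <- mapValues(tfmap)
  df <- data.frame(time = tfmap@times, m, check.names = FALSE)
  colnames(df) <- c("time", sprintf("f%g", tfmap@freqs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
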