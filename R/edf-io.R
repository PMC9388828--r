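## Minimal European Data Format (EDF) I/O.
##
## Covers the subset this package needs: continuous multichannel recordings,
## identical sampling rate on all signals, 16-bit samples, 1-second data
## records. Header fields are space-padded ASCII per the EDF layout
## (256 bytes global + 256 per signal); samples are little-endian int16
## scaled linearly between the physical and digital extrema.

.padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.numField <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .padField(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes a 16-bit EDF with one-second data records. The recording length
#' must be a whole number of seconds and the sampling rate a whole number.
#' Amplitudes are scaled per channel to the full digital range, so the
#' round-trip error is bounded by the 16-bit quantization step.
#'
#' @param recording an [EcogRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdf <- function(recording, path) {
  stopifnot(is(recording, "EcogRecording"))
  x <- signalData(recording)
  fs <- samplingRate(recording)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  nc <- nrow(x)
  if (ncol(x) %% fs != 0)
    stop("EDF writer requires a whole number of seconds of data")
  nrec <- ncol(x) %/% fs

  physMax <- apply(abs(x), 1, max)
  physMax[physMax == 0] <- 1
  digMax <- 32767L

  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))

  hdr <- paste0(
    .padField("0", 8),
    .padField("synthetic ECoG", 80),
    .padField("ezpte dataset", 80),
    .padField("01.01.00", 8),
    .padField("00.00.00", 8),
    .padField(256 * (1 + nc), 8),
    .padField("", 44),
    .padField(nrec, 8),
    .padField(1, 8),
    .padField(nc, 4),
    paste(vapply(rownames(x), .padField, "", width = 16), collapse = ""),
    paste(rep(.padField("", 80), nc), collapse = ""),
    paste(rep(.padField("uV", 8), nc), collapse = ""),
    paste(vapply(-physMax, .numField, "", width = 8), collapse = ""),
    paste(vapply(physMax, .numField, "", width = 8), collapse = ""),
    paste(rep(.padField(-digMax, 8), nc), collapse = ""),
    paste(rep(.padField(digMax, 8), nc), collapse = ""),
    paste(rep(.padField("", 80), nc), collapse = ""),
    paste(rep(.padField(fs, 8), nc), collapse = ""),
    paste(rep(.padField("", 32), nc), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  ## header stores physMax at reduced precision; quantize against the stored
  ## value so the round trip is exact to one digital step
  physStored <- as.numeric(vapply(physMax, .numField, "", width = 8))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nc)) {
      d <- as.integer(round(x[ch, idx] / physStored[ch] * digMax))
      d <- pmin(pmax(d, -digMax), digMax)
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [writeEdf()] (or any same-rate 16-bit EDF)
#'
#' @param path EDF file path.
#' @return An [EcogRecording-class].
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                      # version
  readChar(con, 160, useBytes = TRUE)                    # patient + recording
  readChar(con, 16, useBytes = TRUE)                     # date + time
  readChar(con, 8, useBytes = TRUE)                      # header bytes
  readChar(con, 44, useBytes = TRUE)                     # reserved
  nrec <- as.integer(readChar(con, 8, useBytes = TRUE))
  recDur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  nc <- as.integer(readChar(con, 4, useBytes = TRUE))

  rdChar <- function(w) trimws(vapply(seq_len(nc), function(i)
    readChar(con, w, useBytes = TRUE), ""))
  labels <- rdChar(16)
  rdChar(80)                                             # transducer
  rdChar(8)                                              # physical dimension
  physMin <- as.numeric(rdChar(8))
  physMax <- as.numeric(rdChar(8))
  digMin <- as.numeric(rdChar(8))
  digMax <- as.numeric(rdChar(8))
  rdChar(80)                                             # prefiltering
  spr <- as.integer(rdChar(8))
  rdChar(32)                                             # reserved

  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates are not supported")
  fs <- spr[1] / recDur

  x <- matrix(0, nrow = nc, ncol = nrec * spr[1],
              dimnames = list(labels, NULL))
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nc)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                   signed = TRUE)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      x[ch, idx] <- physMin[ch] + (d - digMin[ch]) * scale[ch]
    }
  }
  EcogRecording(x, fs = fs)
}
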