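## Power extraction and power-spectrum compensation. The maximum wavelet
## power of each electrode is taken from the analysis window at the
## point-A frequency; parameters and power are averaged across epochs
## first, and each averaged parameter is then multiplied by the averaged
## power, electrode by electrode.

#' Maximum wavelet power of one electrode in the analysis window
#'
#' @param tfd a [TFDecomposition-class].
#' @param channel channel index or label.
#' @param window sample indices from [analysisWindow()].
#' @param fStar analysis frequency (Hz); or `"band"` to take the maximum
#'   over all decomposed frequencies as well as time.
#' @return Nonnegative scalar power.
#' @export
maxPower <- function(tfd, channel, window, fStar) {
  stopifnot(is(tfd, "TFDecomposition"))
  ns <- dim(tfd@coefficients)[3]
  if (min(window) < 1 || max(window) > ns)
    stop("window outside the epoch")
  if (identical(fStar, "band")) {
    p <- Mod(tfd@coefficients[channel, , window, drop = TRUE])^2
    return(max(p))
  }
  max(instantaneousPower(tfd, channel, fStar)[window])
}

#' Average per-epoch metrics and power, then apply power compensation
#'
#' Arithmetic mean across epochs per electrode for each of the seven
#' parameters and for the maximum power; the compensated parameter is the
#' averaged parameter times the averaged power (compensation is applied
#' after averaging, not per epoch).
#'
#' @param perEpochMetrics list of data.frames (one per epoch) as returned
#'   by [nodeMetrics()]; identical electrodes and row order required.
#' @param perEpochPower numeric matrix, epochs x electrodes, of maximum
#'   power values.
#' @param zones optional character vector of zone labels per electrode.
#' @return data.frame with one row per electrode: `channel`, `zone` (if
#'   given), averaged `BC ... IS`, `power`, and compensated
#'   `BC_comp ... IS_comp`.
#' @export
aggregateMetrics <- function(perEpochMetrics, perEpochPower, zones = NULL) {
  if (length(perEpochMetrics) < 1) stop("at least one epoch is required")
  electrodes <- rownames(perEpochMetrics[[1]])
  same <- vapply(perEpochMetrics, function(m)
    identical(rownames(m), electrodes), logical(1))
  if (!all(same)) stop("electrode set differs across epochs")
  perEpochPower <- as.matrix(perEpochPower)
  if (ncol(perEpochPower) != length(electrodes) ||
      nrow(perEpochPower) != length(perEpochMetrics))
    stop("perEpochPower must be epochs x electrodes")

  params <- c("BC", "CC", "LE", "OD", "OS", "ID", "IS")
  stack <- simplify2array(lapply(perEpochMetrics, function(m)
    as.matrix(m[, params])))              # electrodes x params x epochs
  avg <- apply(stack, c(1, 2), mean)
  power <- colMeans(perEpochPower)
  comp <- avg * power                      # recycled per column: power_i * row i
  colnames(comp) <- paste0(params, "_comp")

  out <- data.frame(channel = electrodes, check.names = FALSE)
  if (!is.null(zones)) out$zone <- zones
  out <- cbind(out, as.data.frame(avg), power = power, as.data.frame(comp))
  rownames(out) <- electrodes
  out
}
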