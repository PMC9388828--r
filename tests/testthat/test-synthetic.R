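test_that("background noise has the requested spectral slope", {
  fitSlope <- function(x, fs) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0)
    sel <- sp$freq >= 1 & sp$freq <= 90
    unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  }
  white <- generateBackground(1, 60000, 200, noiseExponent = 0, seed = 7)
  expect_lt(abs(fitSlope(signalData(white)[1, ], 200)), 0.2)
  pink <- generateBackground(1, 60000, 200, noiseExponent = 1, seed = 7)
  expect_lt(abs(fitSlope(signalData(pink)[1, ], 200) - (-1)), 0.2)
})

test_that("background generation is deterministic and standardized", {
  a <- generateBackground(3, 2000, 200, 1, seed = 11)
  b <- generateBackground(3, 2000, 200, 1, seed = 11)
  expect_identical(signalData(a), signalData(b))
  expect_equal(unname(apply(signalData(a), 1, stats::sd)), rep(1, 3))
  expect_equal(unname(rowMeans(signalData(a))), rep(0, 3),
               tolerance = 1e-12)
  expect_error(generateBackground(1, 1000, 200, NaN), "finite")
  expect_error(generateBackground(1, 0, 200, 1), "positive")
})

test_that("IED templates have the right morphology", {
  ## count local-maximum regions above 0.5 (plateau-aware: contiguous
  ## runs of samples above 0.5 within the segment)
  countPeaks <- function(w, seg) {
    s <- as.integer(w[seg] > 0.5)
    sum(diff(c(0L, s)) == 1L)
  }
  sw <- makeIedTemplate("spike_wave", fs = 200, spikeWidthMs = 70,
                        slowWaveMs = 300)
  spikeSeg <- seq_len(round(0.07 * 200))
  expect_equal(countPeaks(sw, spikeSeg), 1)
  expect_equal(max(abs(sw)), 1)
  expect_equal(mean(sw), 0, tolerance = 1e-12)

  psw <- makeIedTemplate("polyspike_wave", fs = 200, nSpikes = 3)
  expect_equal(countPeaks(psw, seq_len(3 * round(0.07 * 200))), 3)
  expect_equal(max(abs(psw)), 1)

  expect_error(makeIedTemplate("spike_wave", nSpikes = 2), "nSpikes")
  expect_error(makeIedTemplate("polyspike_wave", nSpikes = 1), "nSpikes")
  expect_error(makeIedTemplate("spike_wave", spikeWidthMs = 400,
                               slowWaveMs = 300), "smaller")
})

test_that("injection respects gains, lags and marker accounting", {
  cfg <- simConfig(nEpochs = 4L, couplingGainNz = 0)
  guard <- max(0.2, 12 * cfg@jitterSdMs / 1000)
  n <- ceiling(cfg@nEpochs * (10 + guard) + guard) * 200
  bg <- generateBackground(16, n, 200, 1, seed = 42)
  sim <- injectIeds(bg, cfg)

  ## zero NZ gain: NZ channels untouched
  nzIdx <- sim$truth@nzChannels
  expect_identical(signalData(sim$recording)[nzIdx, ],
                   signalData(bg)[nzIdx, ])
  ## all markers kept, strictly increasing, epoch gap respected
  expect_length(sim$truth@markerTimes, 4)
  expect_true(all(diff(sim$truth@markerTimes) >= 10))
  expect_equal(sim$truth@droppedEvents, 0L)

  ## EZ->MZ cross-correlation peaks at the configured lag (+-1 sample)
  cfg2 <- simConfig(nEpochs = 3L)
  bg2 <- generateBackground(16, ceiling(3 * 10.24 + 0.24) * 200, 200, 1,
                            seed = 1)
  sim2 <- injectIeds(bg2, cfg2)
  x <- signalData(sim2$recording)
  m <- round(sim2$truth@markerTimes[2] * 200)
  seg <- (m - 150):(m + 150)
  cc <- stats::ccf(x[sim2$truth@ezChannels[1], seg],
                   x[sim2$truth@mzChannels[1], seg],
                   lag.max = 10, plot = FALSE)
  lagHat <- cc$lag[which.max(cc$acf)]
  expect_lte(abs(abs(lagHat) - round(cfg2@lagMzMs / 1000 * 200)), 1)

  ## EZ event peak amplitude over background RMS matches the snr setting
  ezCh <- sim2$truth@ezChannels[1]
  peak <- max(abs(x[ezCh, seg] - signalData(bg2)[ezCh, seg]))
  expect_equal(peak, cfg2@snr, tolerance = 1e-9)
})

test_that("zero-snr limit reduces the dataset to pure background", {
  cfg <- simConfig(nEpochs = 2L, snr = 0)
  guard <- 0.24
  n <- ceiling(2 * (10 + guard) + guard) * 200
  bg <- generateBackground(16, n, 200, 1, seed = 5)
  sim <- injectIeds(bg, cfg)
  expect_equal(signalData(sim$recording), signalData(bg), tolerance = 1e-12)
})

test_that("datasets are reproducible and write valid side-cars", {
  cfg <- simConfig(nChannels = 6L, zones = rep(c("EZ", "MZ", "NZ"), 2),
                   nEpochs = 2L)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  ds1 <- makeDataset(cfg, dir = d1)
  ds2 <- makeDataset(cfg, dir = d2)
  expect_identical(readBin(ds1$paths$edf, "raw", file.size(ds1$paths$edf)),
                   readBin(ds2$paths$edf, "raw", file.size(ds2$paths$edf)))
  expect_equal(nEpochs(ds1$epochs), 2)
  zones <- read.csv(ds1$paths$zones)
  expect_equal(nrow(zones), 6)
  expect_equal(zones$zone, cfg@zones)
  markers <- read.csv(ds1$paths$markers)
  expect_equal(markers$marker_seconds, ds1$truth@markerTimes)

  ## EDF round trip within 16-bit quantization of the per-channel range
  back <- readEdf(ds1$paths$edf)
  orig <- signalData(ds1$recording)
  qstep <- apply(abs(orig), 1, max) / 32767
  err <- abs(signalData(back)[, seq_len(ncol(orig))] - orig)
  expect_true(all(err <= qstep * 1.01 + 1e-12))
  expect_equal(samplingRate(back), 200)
  expect_identical(channelLabels(back), channelLabels(ds1$recording))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulation configs reject inconsistent settings", {
  expect_error(simConfig(zones = rep("EZ", 16)), "zone")
  expect_error(simConfig(lagMzMs = 40, lagNzMs = 30), "lag")
  expect_error(simConfig(couplingGainMz = 0.1, couplingGainNz = 0.5),
               "couplingGainNz")
  expect_error(simConfig(burstFreq = 80), "burstFreq")
})
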