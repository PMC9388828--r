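makeRecording <- function(x, fs = 200) EcogRecording(x, fs = fs)

test_that("common average reference removes the cross-channel mean", {
  r <- makeRecording(rbind(rep(1, 100), rep(3, 100)))
  car <- commonAverageReference(r)
  expect_equal(signalData(car), rbind(ch01 = rep(-1, 100),
                                      ch02 = rep(1, 100)))
  set.seed(3)
  r2 <- makeRecording(matrix(rnorm(5 * 400), 5))
  car2 <- commonAverageReference(r2)
  expect_lt(max(abs(colMeans(signalData(car2)))), 1e-10)
  ## idempotence
  expect_equal(signalData(commonAverageReference(car2)), signalData(car2))
  ## bad channels are excluded before referencing
  r3 <- EcogRecording(matrix(rnorm(3 * 100), 3), fs = 200,
                      badChannels = "ch03")
  expect_equal(nrow(signalData(commonAverageReference(r3))), 2)
  expect_error(commonAverageReference(makeRecording(matrix(1, 1, 50))),
               "at least 2")
})

test_that("rate standardization preserves in-band content and kills aliases", {
  t1k <- seq(0, 10 - 1 / 1000, by = 1 / 1000)
  ## pass-through at target rate
  r <- makeRecording(matrix(rnorm(400), 2), fs = 200)
  expect_identical(standardizeRate(r), r)
  ## 10 Hz tone survives with amplitude within 1%
  tone <- standardizeRate(makeRecording(matrix(sin(2 * pi * 10 * t1k), 1),
                                        fs = 1000))
  expect_equal(samplingRate(tone), 200)
  y <- signalData(tone)[1, ]
  amp <- max(Mod(stats::fft(y))) * 2 / length(y)
  expect_lt(abs(amp - 1), 0.01)
  ## 95 Hz (above the new guard band) attenuated by >= 20 dB
  hi <- standardizeRate(makeRecording(matrix(sin(2 * pi * 95 * t1k), 1),
                                      fs = 1000))
  yh <- signalData(hi)[1, ]
  ampH <- max(Mod(stats::fft(yh))) * 2 / length(yh)
  expect_lt(ampH, 0.1)
  expect_error(standardizeRate(makeRecording(matrix(0, 1, 100), fs = 100)),
               "upsample")
})

test_that("band-pass and notch meet their attenuation contracts", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  mid <- 500:1500
  rms <- function(x) sqrt(mean(x^2))
  ## 60 Hz tone: >= 20 dB down
  r60 <- bandpassNotch(makeRecording(matrix(sin(2 * pi * 60 * t), 1)))
  expect_lt(rms(signalData(r60)[1, mid]) / sqrt(0.5), 0.1)
  ## 21 Hz tone: within 1 dB (12%)
  r21 <- bandpassNotch(makeRecording(matrix(sin(2 * pi * 21 * t), 1)))
  expect_lt(abs(rms(signalData(r21)[1, mid]) / sqrt(0.5) - 1), 0.12)
  ## DC offset removed
  rdc <- bandpassNotch(makeRecording(matrix(rep(5, 2000), 1)))
  expect_lt(abs(mean(signalData(rdc)[1, mid])), 5e-3)
  ## zero phase: symmetric pulse peak unmoved
  p <- numeric(2000); p[1000] <- 1
  rp <- bandpassNotch(makeRecording(matrix(p, 1)))
  expect_lte(abs(which.max(signalData(rp)[1, ]) - 1000), 1)
  expect_error(bandpassNotch(makeRecording(matrix(0, 1, 100)), low = 30,
                             high = 10), "low must be")
  expect_error(bandpassNotch(makeRecording(matrix(0, 1, 100)), notch = 70),
               "notch")
})

test_that("epoch extraction centers markers and handles edges", {
  fs <- 200
  x <- matrix(seq_len(2 * 400 * fs), nrow = 2)   # distinguishable samples
  r <- makeRecording(x, fs = fs)
  ## marker too close to the edge of a short recording
  short <- makeRecording(matrix(rnorm(2 * 10 * fs), 2), fs = fs)
  expect_warning(expect_error(
    extractEpochs(short, markers = 5, duration = 10), "no valid markers"),
    "skipped")
  ## interior markers: exact count, shape and content
  markers <- seq(10, 300, by = 10)[1:30]
  ep <- extractEpochs(r, markers, duration = 10)
  expect_equal(nEpochs(ep), 30)
  expect_equal(dim(ep@epochs)[2], 2000)
  expect_equal(ep@markerIndex, 1001L)
  k <- 7
  c0 <- round(markers[k] * fs)
  expected <- x[, (c0 - 1000):(c0 + 999)] * 1
  dimnames(expected) <- dimnames(epochData(ep, k))
  expect_equal(epochData(ep, k), expected)
  ## mixed valid/invalid markers: invalid skipped with a warning
  expect_warning(ep2 <- extractEpochs(r, c(2, 50, 100), duration = 10),
                 "skipped")
  expect_equal(nEpochs(ep2), 2)
})

test_that("full preprocessing chain yields clean centered epochs", {
  cfg <- simConfig(nChannels = 6L, zones = rep(c("EZ", "MZ", "NZ"), 2),
                   nEpochs = 3L)
  ds <- makeDataset(cfg)
  ep <- preprocessRecording(ds$recording, ds$truth@markerTimes)
  expect_s4_class(ep, "EpochSet")
  expect_equal(nEpochs(ep), 3)
  expect_equal(samplingRate(ep), 200)
  expect_false(any(!is.finite(ep@epochs)))
  ## IED energy concentrates near the marker after filtering
  e1 <- epochData(ep, 1)[1, ]                      # an EZ channel
  expect_gt(max(abs(e1[900:1100])), max(abs(e1[1:200])))
})
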