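test_that("phase binning is uniform, right-closed and boundary-safe", {
  expect_equal(binPhases(rep(0, 50), 8), rep(3L, 50))
  expect_equal(binPhases(c(-pi + 1e-9, pi), 2), c(0L, 1L))
  ## one full cycle sampled uniformly occupies every bin equally (+-1)
  ramp <- seq(-pi + 1e-9, pi, length.out = 160)
  counts <- tabulate(binPhases(ramp, 8) + 1L, 8)
  expect_true(all(abs(counts - 20) <= 1))
  expect_error(binPhases(numeric(0), 4), "empty")
  expect_error(binPhases(c(0, 4), 4), "lie in")
})

test_that("transfer entropy matches a brute-force histogram oracle", {
  set.seed(20)
  for (rep in 1:50) {
    n <- 120
    B <- sample(3:6, 1)
    d <- sample(1:4, 1)
    x <- sample(0:(B - 1), n, replace = TRUE)
    y <- sample(0:(B - 1), n, replace = TRUE)
    expect_equal(transferEntropy(x, y, d, B), pluginTeOracle(x, y, d, B),
                 tolerance = 1e-12)
  }
})

test_that("deterministic copy attains the closed-form transfer entropy", {
  ## y_{t+d} = x_t with x iid uniform over 4 symbols: TE(X->Y) = 2 bits
  set.seed(21)
  n <- 20000; d <- 3
  x <- sample(0:3, n, replace = TRUE)
  y <- c(sample(0:3, d, replace = TRUE), x[1:(n - d)])
  expect_equal(transferEntropy(x, y, d, 4), 2, tolerance = 0.01)
  expect_lt(transferEntropy(y, x, d, 4), 0.01)
  ## identical inputs give symmetric TE
  expect_equal(transferEntropy(x, x, d, 4), transferEntropy(x, x, d, 4))
})

test_that("transfer entropy is nonnegative and relabeling-invariant", {
  set.seed(22)
  for (rep in 1:20) {
    B <- 5
    x <- sample(0:(B - 1), 150, replace = TRUE)
    y <- sample(0:(B - 1), 150, replace = TRUE)
    te <- transferEntropy(x, y, 2, B)
    expect_gte(te, 0)
    perm <- sample(0:(B - 1))
    expect_equal(transferEntropy(perm[x + 1], perm[y + 1], 2, B), te,
                 tolerance = 1e-12)
  }
})

test_that("estimator error shrinks with window length for the copy map", {
  lens <- c(100, 500, 2500)
  errs <- sapply(lens, function(n) {
    mean(sapply(1:20, function(s) {
      set.seed(s)
      d <- 2
      x <- sample(0:3, n, replace = TRUE)
      y <- c(sample(0:3, d, replace = TRUE), x[1:(n - d)])
      abs(transferEntropy(x, y, d, 4) - 2)
    }))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("dPTE is antisymmetric with a well-defined null", {
  set.seed(23)
  ph1 <- runif(100, -pi, pi); ph2 <- runif(100, -pi, pi)
  p <- pteParams(delay = 2)
  a <- ptePair(ph1, ph2, p)
  b <- ptePair(ph2, ph1, p)
  expect_equal(a$dpteXY, 1 - b$dpteXY, tolerance = 1e-12)
  expect_equal(a$pteXY, b$pteYX)
  ## both directions zero -> 0.5 (constant phases land in one bin)
  z <- ptePair(rep(0, 60), rep(0, 60), pteParams(delay = 1, nBins = 4))
  expect_equal(z$dpteXY, 0.5)
})

test_that("independent phases center dPTE on one half", {
  set.seed(24)
  p <- pteParams(delay = 2)
  dp <- replicate(200, {
    ptePair(runif(100, -pi, pi), runif(100, -pi, pi), p)$dpteXY
  })
  expect_lt(abs(mean(dp) - 0.5), 0.02)
})

test_that("lagged narrow-band coupling is detected in the right direction", {
  ## x drives y at a quarter-cycle lag of the 21 Hz carrier
  fs <- 200
  d <- pteDelay(fs, 21)
  hits <- 0
  for (s in 1:100) {
    set.seed(300 + s)
    src <- narrowbandBurst(2000, fs, 21, hann = FALSE)
    lag <- d
    y <- c(rep(0, lag), src[1:(2000 - lag)])
    both <- morletDecompose(rbind(src, y), fs = fs, freqs = c(19, 21, 23))
    win <- 801:900
    pp <- ptePair(instantaneousPhase(both, 1, 21)[win],
                  instantaneousPhase(both, 2, 21)[win],
                  pteParams(), fs = fs, freq = 21)
    if (pp$pteXY > pp$pteYX) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("the analysis window is centered on point A with fixed width", {
  w <- analysisWindow(5.0, fs = 200, windowMs = 500, nSamples = 2000)
  expect_equal(w, 951:1050)            # samples [950, 1050) zero-based
  expect_length(w, 100)
  w2 <- analysisWindow(0.25, fs = 200, windowMs = 500, nSamples = 2000)
  expect_equal(range(w2), c(1, 100))
  expect_error(analysisWindow(0.1, fs = 200, windowMs = 500,
                              nSamples = 2000), "does not fit")
})

test_that("the synchrony map normalizes to 1 and locks onto the IED", {
  ## full IED epochs (spike + burst): point A is event-locked in time and
  ## the raw map peak clearly exceeds the white-noise synchrony floor.
  ## Frequency attribution is bias-limited (see the methods vignette), so
  ## the locked quantity asserted here is time.
  timeHits <- 0
  for (s in 1:4) {
    cfg <- simConfig(nChannels = 6L, zones = rep(c("EZ", "MZ", "NZ"), 2),
                     nEpochs = 1L, seed = 100L + s)
    ds <- makeDataset(cfg)
    ep <- extractEpochs(ds$recording, ds$truth@markerTimes)
    map <- tfSynchronyMap(morletDecompose(ep, i = 1))
    expect_equal(max(mapValues(map)), 1)
    expect_true(all(mapValues(map) >= 0 & mapValues(map) <= 1))
    if (abs(pointA(map)["time"] - 5) <= 0.25) timeHits <- timeHits + 1
    ## raw white-noise map values sit below the coupled epoch's raw peak
    noise <- signalData(generateBackground(6, 2000, 200, 1, seed = 900 + s))
    mn <- tfSynchronyMap(morletDecompose(noise, fs = 200))
    expect_lt(median(mapValues(mn) * mn@scale) / map@scale, 0.8)
  }
  expect_gte(timeHits, 3)
})

test_that("degenerate synchrony maps are rejected", {
  z <- matrix(0, 3, 2000)
  tfd <- morletDecompose(z, fs = 200, freqs = c(19, 21))
  expect_error(tfSynchronyMap(tfd), "point A is undefined")
})
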