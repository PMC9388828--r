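test_that("proportional thresholding keeps the top weights only", {
  ## N = 4, off-diagonal entries 1..12, q = 0.70 -> top 4 survive
  W <- matrix(0, 4, 4)
  W[row(W) != col(W)] <- 1:12
  thr <- thresholdMatrix(W, 0.70)
  expect_equal(sum(thr$A), 4)
  expect_true(all(thr$Wthr[thr$A == 1] >= 9))
  ## q = 0 retains all positive entries
  thr0 <- thresholdMatrix(W, 0)
  expect_equal(sum(thr0$A), 12)
  ## retained weights are unchanged
  expect_true(all(thr$Wthr == W * thr$A))
  ## all-equal off-diagonal: strict rule removes everything, with warning
  We <- matrix(1, 3, 3); diag(We) <- 0
  expect_warning(thrE <- thresholdMatrix(We, 0.70), "no edges retained")
  expect_equal(sum(thrE$A), 0)
  expect_error(thresholdMatrix(W, 1), "q must")
})

test_that("threshold counts match a sort-based oracle across q values", {
  set.seed(30)
  for (rep in 1:50) {
    n <- sample(5:10, 1)
    W <- randomDigraph(n, density = 1)   # all off-diag present, distinct
    for (q in c(0.30, 0.50, 0.70)) {
      thr <- thresholdMatrix(W, q)
      off <- sort(W[row(W) != col(W)])
      tau <- off[floor(q * length(off))]
      expect_equal(sum(thr$A), sum(off > tau))
    }
  }
})

test_that("degrees and strengths are direct sums of the adjacency", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  ds <- degreesStrengths(A * 0.4, A)
  expect_equal(ds$OD, c(1, 0, 0))
  expect_equal(ds$ID, c(0, 1, 0))
  expect_equal(ds$OS, c(0.4, 0, 0))
  set.seed(31)
  W <- randomDigraph(8, 0.5)
  ds2 <- degreesStrengths(W)
  expect_equal(sum(ds2$OD), sum(ds2$ID))        # handshake
  expect_equal(sum(ds2$OS), sum(ds2$IS))
  expect_equal(sum(ds2$OS), sum(W))
})

test_that("clustering matches the complete-graph value and the oracle", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(clusteringCoefficientDirected(K3), rep(1, 3))
  ## degenerate degree -> 0
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  expect_equal(clusteringCoefficientDirected(A)[1], 0)
  for (s in 1:100) {
    W <- randomDigraph(8, 0.4, seed = 100 + s)
    expect_equal(clusteringCoefficientDirected(W), bruteClustering(W),
                 tolerance = 1e-9)
  }
})

test_that("local efficiency matches complete/star cases and the oracle", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(localEfficiencyDirected(K4), rep(1, 4))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1   # hub -> leaves only
  le <- localEfficiencyDirected(star)
  expect_equal(le[2:4], rep(0, 3))
  for (s in 1:100) {
    W <- randomDigraph(8, 0.4, seed = 200 + s)
    expect_equal(localEfficiencyDirected(W), bruteLocalEfficiency(W),
                 tolerance = 1e-9)
  }
})

test_that("betweenness matches path/complete cases and the oracle", {
  ## directed path a -> b -> c: b mediates one ordered pair
  P <- matrix(0, 3, 3); P[1, 2] <- 1; P[2, 3] <- 1
  expect_equal(betweennessCentrality(P), c(0, 0.5, 0))
  ## complete equal-weight digraph: all geodesics are direct edges
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(betweennessCentrality(K5), rep(0, 5))
  for (s in 1:100) {
    W <- randomDigraph(7, 0.35, seed = 300 + s)
    expect_equal(betweennessCentrality(W), bruteBetweenness(W),
                 tolerance = 1e-9)
  }
})

test_that("metrics respect node relabeling and weight scaling", {
  set.seed(32)
  W <- randomDigraph(8, 0.45)
  m <- nodeMetrics(W)
  ## permutation invariance
  p <- sample(8)
  mp <- nodeMetrics(W[p, p])
  for (col in colnames(m)) expect_equal(mp[[col]], m[[col]][p],
                                        tolerance = 1e-9)
  ## scale behavior: x k leaves A-derived metrics alone, scales strengths
  k <- 3.7
  mk <- nodeMetrics(k * W)
  expect_equal(mk$OD, m$OD)
  expect_equal(mk$ID, m$ID)
  expect_equal(mk$CC, m$CC, tolerance = 1e-9)     # rescaled form
  expect_equal(mk$BC, m$BC, tolerance = 1e-9)
  expect_equal(mk$OS, k * m$OS, tolerance = 1e-9)
  expect_equal(mk$IS, k * m$IS, tolerance = 1e-9)
  ## adding an out-edge never decreases OD or OS
  W2 <- W
  zero <- which(W2 == 0 & row(W2) != col(W2))[1]
  W2[zero] <- max(W2) + 1
  m2 <- nodeMetrics(W2)
  expect_true(all(m2$OD >= m$OD))
  expect_true(all(m2$OS >= m$OS - 1e-12))
})

test_that("adjacency built from lagged phases is directional", {
  fs <- 200
  set.seed(33)
  src <- narrowbandBurst(2000, fs, 21, hann = FALSE)
  lag <- 3
  y <- c(rep(0, lag), src[1:(2000 - lag)])
  noise <- 0.3 * signalData(generateBackground(2, 2000, fs, 1, seed = 34))
  x2 <- rbind(src + noise[1, ], y + noise[2, ])
  tfd <- morletDecompose(x2, fs = fs, freqs = c(19, 21, 23))
  win <- analysisWindow(5, fs, 500, 2000)
  adj <- buildAdjacency(tfd, win, 21, thresholdQ = 0)
  W <- adjacencyWeights(adj)
  expect_gt(W[1, 2], W[2, 1])
  expect_equal(diag(W), c(0, 0), ignore_attr = TRUE)
  ## identical channels: symmetric within numerical precision
  x3 <- rbind(src, src)
  tfd3 <- morletDecompose(x3, fs = fs, freqs = c(19, 21, 23))
  W3 <- adjacencyWeights(buildAdjacency(tfd3, win, 21, thresholdQ = 0))
  expect_lt(abs(W3[1, 2] - W3[2, 1]), 1e-12)
})
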