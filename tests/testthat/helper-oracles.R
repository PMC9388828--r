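## Independent brute-force oracles used to cross-check the package's
## estimators and graph metrics, plus small fixture builders. All oracles
## are deliberately naive (loops, enumeration) and share no code with the
## implementation.

## plug-in transfer entropy by direct histogram counting (bits)
pluginTeOracle <- function(x, y, d, B) {
  m <- length(x) - d
  yf <- y[(1 + d):(m + d)]; yp <- y[1:m]; xp <- x[1:m]
  s <- 0
  for (a in 0:(B - 1)) for (b in 0:(B - 1)) for (cc in 0:(B - 1)) {
    n3 <- sum(yf == a & yp == b & xp == cc)
    if (n3 == 0) next
    nyy <- sum(yf == a & yp == b)
    nyx <- sum(yp == b & xp == cc)
    ny <- sum(yp == b)
    s <- s + n3 / m * log2((n3 * ny) / (nyx * nyy))
  }
  s
}

## Fagiolo directed weighted clustering by explicit triangle enumeration
bruteClustering <- function(W) {
  A <- (W > 0) * 1; diag(A) <- 0
  Wh <- if (max(W) > 0) W / max(W) else W
  n <- nrow(W)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      num <- num +
        (Wh[i, j]^(1 / 3) + Wh[j, i]^(1 / 3)) *
        (Wh[j, k]^(1 / 3) + Wh[k, j]^(1 / 3)) *
        (Wh[k, i]^(1 / 3) + Wh[i, k]^(1 / 3))
    }
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    cc[i] <- if (den > 0) num / den else 0
  }
  cc
}

## local efficiency with Floyd-Warshall all-pairs shortest paths
bruteLocalEfficiency <- function(W) {
  A <- (W > 0) * 1; diag(A) <- 0
  Wh <- if (max(W) > 0) W / max(W) else W
  n <- nrow(W)
  L <- ifelse(Wh > 0, 1 / Wh, Inf)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0 | A[, i] > 0)
    m <- length(nb)
    if (m < 2) next
    D <- L[nb, nb, drop = FALSE]
    diag(D) <- 0
    for (k in seq_len(m)) for (a in seq_len(m)) for (b in seq_len(m))
      if (D[a, k] + D[k, b] < D[a, b]) D[a, b] <- D[a, k] + D[k, b]
    inv <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
    le[i] <- sum(inv) / (m * (m - 1))
  }
  le
}

## betweenness by exhaustive simple-path enumeration; geodesic ties are
## split proportionally by path counts
bruteBetweenness <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    best <- Inf
    paths <- list()
    rec <- function(v, visited, len, path) {
      if (v == t) {
        if (len < best - 1e-12) {
          best <<- len
          paths <<- list(path)
        } else if (abs(len - best) <= 1e-12) {
          paths[[length(paths) + 1L]] <<- path
        }
        return(invisible())
      }
      for (u in seq_len(n)) {
        if (!visited[u] && is.finite(L[v, u]) &&
            len + L[v, u] <= best + 1e-12) {
          visited[u] <- TRUE
          rec(u, visited, len + L[v, u], c(path, u))
          visited[u] <- FALSE
        }
      }
    }
    vis <- rep(FALSE, n); vis[s] <- TRUE
    rec(s, vis, 0, s)
    if (!is.finite(best)) next
    sigma <- length(paths)
    for (p in paths)
      for (v in p[-c(1, length(p))]) bc[v] <- bc[v] + 1 / sigma
  }
  bc / ((n - 1) * (n - 2))
}

## random directed weight matrix with zero diagonal
randomDigraph <- function(n, density = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  mask <- matrix(stats::runif(n * n) < density, n, n)
  W[mask] <- stats::runif(sum(mask), 0.2, 1)
  diag(W) <- 0
  W
}

## exact two-tailed Mann-Whitney p by enumerating all group assignments
exactMannWhitneyOracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  uStat <- function(ga, gb) sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  u0 <- uStat(a, b)
  mid <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) uStat(pooled[idx], pooled[-idx]))
  mean(abs(us - mid) >= abs(u0 - mid) - 1e-12)
}

## one simulated epoch with a lag-coupled 21 Hz burst at the center and
## no spike transient; channels 1-2 lead, channels 3-4 follow
coupledBurstEpoch <- function(seed, fs = 200, nChannels = 4, burstFreq = 21,
                              lagSamples = 3, gain = 0.7, amp = 2) {
  bg <- generateBackground(nChannels, 10 * fs, fs, noiseExponent = 1,
                           seed = seed)
  x <- signalData(bg)
  b <- amp * narrowbandBurst(fs / 2, fs, burstFreq)
  center <- 5 * fs
  idx <- (center - length(b) / 2 + 1):(center + length(b) / 2)
  lead <- seq_len(nChannels / 2)
  for (ch in lead) x[ch, idx] <- x[ch, idx] + b
  for (ch in setdiff(seq_len(nChannels), lead))
    x[ch, idx + lagSamples] <- x[ch, idx + lagSamples] + gain * b
  x
}
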