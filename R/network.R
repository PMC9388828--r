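## Directed weighted graph metrics on the thresholded PTE adjacency matrix.
## Seven per-node parameters: out-/in-degree (OD, ID) on the binarized
## matrix; out-/in-strength (OS, IS) on retained weights; Fagiolo's
## directed weighted clustering coefficient (CC); local efficiency (LE) and
## betweenness centrality (BC) on inverse-weight path lengths.

#' Build the directed PTE adjacency matrix for an analysis window
#'
#' `W[i, j]` is the transfer entropy from channel i to channel j computed
#' on binned instantaneous phases at `fStar` within the analysis window;
#' the proportional threshold is applied immediately, yielding the
#' thresholded and binarized views.
#'
#' @param tfd a [TFDecomposition-class] of the epoch.
#' @param window sample indices from [analysisWindow()].
#' @param fStar analysis frequency (Hz), one of the decomposed
#'   frequencies.
#' @param params a [PTEParams-class].
#' @param thresholdQ removed-fraction quantile, default 0.70.
#' @return A [PTEAdjacency-class].
#' @export
buildAdjacency <- function(tfd, window, fStar, params = pteParams(),
                           thresholdQ = 0.70) {
  stopifnot(is(tfd, "TFDecomposition"), is(params, "PTEParams"))
  fi <- .freqIndex(tfd, fStar)
  fs <- tfd@fs
  n <- length(window)
  delay <- if (is.na(params@delay)) pteDelay(fs, fStar) else
    as.integer(params@delay)
  nBins <- if (is.na(params@nBins)) pteNBins(n, delay) else
    as.integer(params@nBins)
  if (n < 10 * nBins)
    warning("window holds fewer than 10 samples per phase bin; ",
            "the PTE histogram may be undersampled")
  ph <- .phaseMatrix(tfd, fi)[window, , drop = FALSE]
  W <- pteMatrixCpp(binPhases(ph, nBins), delay, nBins)
  labs <- dimnames(tfd@coefficients)[[1]]
  dimnames(W) <- list(labs, labs)
  thr <- thresholdMatrix(W, thresholdQ)
  new("PTEAdjacency", W = W, Wthr = thr$Wthr, A = thr$A,
      thresholdQ = thresholdQ, fStar = fStar)
}

#' Proportional threshold of a directed weight matrix
#'
#' Removes the lowest `q` fraction of off-diagonal entries: the retention
#' threshold is the `floor(q * m)`-th smallest off-diagonal value (m =
#' number of off-diagonal entries) and only strictly greater entries keep
#' their weights. `q = 0` retains everything. If all off-diagonal entries
#' are equal the strict rule removes them all, with a warning.
#'
#' @param W square nonnegative weight matrix, zero diagonal.
#' @param q removed fraction in `[0, 1)`, default 0.70.
#' @return `list(Wthr =, A =)`: thresholded weights and binary indicator.
#' @export
thresholdMatrix <- function(W, q = 0.70) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  off <- W[row(W) != col(W)]
  if (q == 0) {
    A <- (W > 0) * 1
    diag(A) <- 0
    return(list(Wthr = W * A, A = A))
  }
  m <- length(off)
  k <- floor(q * m)
  if (k < 1) k <- 1
  tau <- sort(off, partial = k)[k]
  keep <- W > tau
  diag(keep) <- FALSE
  if (!any(keep)) {
    warning("all off-diagonal entries at or below the threshold; ",
            "no edges retained")
  }
  A <- keep * 1
  list(Wthr = W * A, A = A)
}

#' Degrees and strengths of each node
#'
#' OD/ID count outgoing/incoming retained edges (binarized matrix); OS/IS
#' sum their weights.
#'
#' @param Wthr thresholded weight matrix.
#' @param A binary adjacency; defaults to `(Wthr > 0) * 1`.
#' @return data.frame with columns `OD, ID, OS, IS`, one row per node.
#' @export
degreesStrengths <- function(Wthr, A = NULL) {
  if (is.null(A)) { A <- (Wthr > 0) * 1; diag(A) <- 0 }
  data.frame(OD = rowSums(A), ID = colSums(A),
             OS = rowSums(Wthr), IS = colSums(Wthr),
             row.names = rownames(Wthr))
}

#' Directed weighted clustering coefficient (Fagiolo)
#'
#' Weights are rescaled to [0, 1] by the maximum retained weight; with
#' `S = Wh^(1/3) + (Wh')^(1/3)` (elementwise roots),
#' `CC_i = (S^3)_ii / (2 * (dtot_i * (dtot_i - 1) - 2 * dbi_i))` where
#' `dtot` is total degree and `dbi` the count of reciprocal edges.
#' Nodes with `dtot <= 1` (or no non-reciprocal pair) get CC = 0.
#'
#' @param Wthr thresholded weight matrix.
#' @param A binary adjacency; defaults to `(Wthr > 0) * 1`.
#' @param weighted if `FALSE`, use the binarized matrix instead of
#'   rescaled weights.
#' @return Numeric CC per node, in [0, 1].
#' @export
clusteringCoefficientDirected <- function(Wthr, A = NULL, weighted = TRUE) {
  if (is.null(A)) { A <- (Wthr > 0) * 1; diag(A) <- 0 }
  Wh <- if (weighted && max(Wthr) > 0) Wthr / max(Wthr) else A
  S <- Wh^(1 / 3) + t(Wh)^(1 / 3)
  num <- diag(S %*% S %*% S)
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  cc <- ifelse(den > 0, num / den, 0)
  unname(cc)
}

.lengthGraph <- function(Wthr) {
  ## igraph on inverse-weight edge lengths; absent edges are no edges
  g <- igraph::graph_from_adjacency_matrix(Wthr, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Directed local efficiency
#'
#' For each node, the efficiency of the subgraph induced by its neighbors
#' (union of out- and in-neighbors): the mean over ordered neighbor pairs
#' of inverse shortest-path length, paths computed within the subgraph on
#' inverse-weight edge lengths. Nodes with fewer than 2 neighbors get 0.
#'
#' @inheritParams clusteringCoefficientDirected
#' @return Numeric LE per node, in [0, 1] (weights rescaled by the
#'   maximum, so direct hops have efficiency at most 1).
#' @export
localEfficiencyDirected <- function(Wthr, A = NULL, weighted = TRUE) {
  if (is.null(A)) { A <- (Wthr > 0) * 1; diag(A) <- 0 }
  n <- nrow(Wthr)
  Wh <- if (weighted && max(Wthr) > 0) Wthr / max(Wthr) else A
  g <- .lengthGraph(Wh)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0 | A[, i] > 0)
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(g, nb)
    d <- igraph::distances(sub, mode = "out",
                           weights = if (igraph::ecount(sub) > 0)
                             igraph::E(sub)$length else NULL)
    inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
    le[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  le
}

#' Betweenness centrality on inverse-weight path lengths
#'
#' Weighted-directed betweenness (Brandes; equal-length geodesic ties are
#' split proportionally by path counts), normalized by
#' `(N - 1) * (N - 2)`.
#'
#' @param Wthr thresholded weight matrix.
#' @return Numeric BC per node, in [0, 1].
#' @export
betweennessCentrality <- function(Wthr) {
  n <- nrow(Wthr)
  if (n < 3) return(numeric(n))
  g <- .lengthGraph(Wthr)
  b <- igraph::betweenness(g, directed = TRUE,
                           weights = if (igraph::ecount(g) > 0)
                             igraph::E(g)$length else NULL)
  unname(b) / ((n - 1) * (n - 2))
}

#' All seven node metrics of a thresholded adjacency matrix
#'
#' @param adj a [PTEAdjacency-class], or a thresholded weight matrix.
#' @param weighted use retained weights (default) or the binarized graph
#'   for CC and LE.
#' @return data.frame with columns `BC, CC, LE, OD, OS, ID, IS`, one row
#'   per node.
#' @export
nodeMetrics <- function(adj, weighted = TRUE) {
  if (is(adj, "PTEAdjacency")) {
    Wthr <- adj@Wthr; A <- adj@A
  } else {
    Wthr <- adj; A <- (Wthr > 0) * 1; diag(A) <- 0
  }
  ds <- degreesStrengths(Wthr, A)
  data.frame(
    BC = betweennessCentrality(Wthr),
    CC = clusteringCoefficientDirected(Wthr, A, weighted),
    LE = localEfficiencyDirected(Wthr, A, weighted),
    OD = ds$OD, OS = ds$OS, ID = ds$ID, IS = ds$IS,
    row.names = rownames(Wthr))
}
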