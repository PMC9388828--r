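## Zone-level statistics: two-tailed Mann-Whitney U tests per parameter and
## zone pair (EZ-MZ, EZ-NZ, MZ-NZ) with the three-tier star system, and
## in-sample logistic classification of EZ vs the rest with a 0.5
## probability cutoff.

#' Two-tailed Mann-Whitney U test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections. U is reported for the first group (number of pairs where
#' `a > b`, ties counted 1/2).
#'
#' @param a,b numeric samples.
#' @return `list(U =, p =)` with the two-tailed p-value.
#' @export
mannWhitneyU <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1))
  ties <- any(duplicated(pooled))
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = min(1, ht$p.value))
}

.sigTier <- function(p) {
  if (p < 1e-5) "***" else if (p < 1e-3) "**" else if (p < 0.05) "*" else ""
}

#' Compare compensated parameters across zones
#'
#' For each of the seven parameters and each zone pair, a two-tailed
#' Mann-Whitney U test; direction (which group tends larger, from the U
#' statistic) is reported only when p < 0.05; significance tiers are
#' `*` (p < 0.05), `**` (p < 0.001), `***` (p < 0.00001). Missing zones
#' skip their pairs with a warning.
#'
#' @param metrics data.frame from [aggregateMetrics()] containing a
#'   `zone` column.
#' @param useCompensated compare the power-compensated parameters
#'   (default) or the plain epoch-averaged ones.
#' @param pAdjust `"none"` (default, mirroring the reference analysis) or
#'   `"BH"` to append Benjamini-Hochberg-adjusted p-values across the 21
#'   tests as a `p_adj` column (direction and tier stay based on raw p).
#' @return data.frame with columns `parameter, pair, U, p, direction,
#'   tier` (plus `p_adj` when requested); one row per parameter x pair.
#' @export
compareZones <- function(metrics, useCompensated = TRUE,
                         pAdjust = c("none", "BH")) {
  pAdjust <- match.arg(pAdjust)
  stopifnot("zone" %in% colnames(metrics))
  params <- c("BC", "CC", "LE", "OD", "OS", "ID", "IS")
  cols <- if (useCompensated) paste0(params, "_comp") else params
  pairs <- list(c("EZ", "MZ"), c("EZ", "NZ"), c("MZ", "NZ"))
  out <- list()
  for (pr in pairs) {
    ga <- metrics[metrics$zone == pr[1], , drop = FALSE]
    gb <- metrics[metrics$zone == pr[2], , drop = FALSE]
    if (nrow(ga) == 0 || nrow(gb) == 0) {
      warning("zone pair ", pr[1], "-", pr[2], " skipped: missing zone")
      next
    }
    for (k in seq_along(params)) {
      a <- ga[[cols[k]]]; b <- gb[[cols[k]]]
      mw <- mannWhitneyU(a, b)
      dir <- if (mw$p < 0.05)
        if (mw$U > length(a) * length(b) / 2) "greater" else "less"
      else ""
      out[[length(out) + 1L]] <- data.frame(
        parameter = params[k], pair = paste(pr, collapse = "-"),
        U = mw$U, p = mw$p, direction = dir, tier = .sigTier(mw$p))
    }
  }
  out <- do.call(rbind, out)
  if (pAdjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

## ridge-penalized logistic fit by Newton iterations; used when the
## unpenalized likelihood degenerates under complete separation
.ridgeLogistic <- function(X, y, lambda = 1e-3, maxIter = 100) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (it in seq_len(maxIter)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X1, X1 * w) + 2 * pen
    gr <- crossprod(X1, y - p) - 2 * pen %*% beta
    step <- solve(H, gr)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  drop(1 / (1 + exp(-(X1 %*% beta))))
}

#' In-sample logistic classification of EZ vs other electrodes
#'
#' Maximum-likelihood logistic regression on standardized features,
#' evaluated in-sample; electrodes with fitted probability above `cutoff`
#' are classified as EZ. Under complete separation the fit is stabilized
#' with a small quadratic (ridge) penalty and flagged.
#'
#' @param features numeric matrix or data.frame of per-electrode features
#'   (e.g. the seven compensated parameters).
#' @param labels logical or 0/1 vector, `TRUE` for EZ.
#' @param cutoff classification probability cutoff, default 0.5.
#' @return `list(probabilities, predicted, accuracyEz, accuracyOther,
#'   separation)`; accuracies are percentages per class.
#' @export
logisticClassify <- function(features, labels, cutoff = 0.5) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("features must be finite")
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  Xs <- scale(X[, keep, drop = FALSE])

  separation <- FALSE
  probs <- withCallingHandlers(
    {
      fit <- stats::glm(y ~ Xs, family = stats::binomial())
      stats::predict(fit, type = "response")
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) probs <- .ridgeLogistic(Xs, y)
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)

  predicted <- probs > cutoff
  accEz <- 100 * mean(predicted[y == 1])
  accOther <- 100 * mean(!predicted[y == 0])
  list(probabilities = unname(probs), predicted = unname(predicted),
       accuracyEz = accEz, accuracyOther = accOther,
       separation = separation)
}

#' Box-plot summary per zone and parameter
#'
#' Median, quartiles and whisker ends (1.5 IQR rule) of each compensated
#' parameter within each zone.
#'
#' @inheritParams compareZones
#' @return data.frame with columns `parameter, zone, n, whiskerLow, q1,
#'   median, q3, whiskerHigh`.
#' @export
zoneBoxplotSummary <- function(metrics, useCompensated = TRUE) {
  stopifnot("zone" %in% colnames(metrics))
  params <- c("BC", "CC", "LE", "OD", "OS", "ID", "IS")
  cols <- if (useCompensated) paste0(params, "_comp") else params
  out <- list()
  for (z in intersect(c("EZ", "MZ", "NZ"), unique(metrics$zone))) {
    g <- metrics[metrics$zone == z, , drop = FALSE]
    for (k in seq_along(params)) {
      v <- g[[cols[k]]]
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- qs[3] - qs[1]
      out[[length(out) + 1L]] <- data.frame(
        parameter = params[k], zone = z, n = length(v),
        whiskerLow = min(v[v >= qs[1] - 1.5 * iqr]),
        q1 = qs[1], median = qs[2], q3 = qs[3],
        whiskerHigh = max(v[v <= qs[3] + 1.5 * iqr]))
    }
  }
  do.call(rbind, out)
}
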