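# Group-level inference: sign-flip paired permutation tests, Holm
# correction, cluster-based permutation over time, and Bayesian population
# prevalence.

# All 2^n sign patterns as a (2^n) x n matrix of +/-1 (includes identity).
signMatrixExhaustive <- function(n) {
  m <- 2^n
  k <- 0:(m - 1)
  S <- matrix(0, m, n)
  for (i in seq_len(n)) S[, i] <- ((k %/% 2^(i - 1)) %% 2) * 2 - 1
  S
}

signMatrixRandom <- function(nPerm, n, seed) {
  withSeed(seed, matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n))
}

#' Paired permutation test by sign flips
#'
#' Tests the mean paired difference `mean(a - b)` against the sign-flip
#' null. When `2^n <= nPerm` the null is enumerated exhaustively (the
#' identity flip included, so p is an exact, valid count ratio); otherwise
#' `nPerm` random sign patterns are drawn and the add-one convention
#' `p = (1 + #{null >= obs}) / (1 + nPerm)` is used.
#'
#' @param a per-subject values.
#' @param b per-subject values, or a single constant (e.g. chance level
#'   0.5).
#' @param nPerm permutation budget (default 2048 = 2^11).
#' @param side `"greater"` (default; directional hypotheses such as AUC
#'   above chance), `"less"` or `"two.sided"`.
#' @param seed RNG seed (used only for non-exhaustive draws).
#' @return a `"prosynPermTest"` list: `statistic`, `p`, `nPerm`,
#'   `exhaustive`, `side`, `n`.
#' @examples
#' pairedPermutationTest(c(2, 3, 4), 1, side = "greater")$p # 1/8
#' @export
pairedPermutationTest <- function(a, b = 0.5, nPerm = 2048,
                                  side = c("greater", "less", "two.sided"),
                                  seed = 1) {
  side <- match.arg(side)
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
  n <- length(a)
  if (n < 2L) stopf("at least 2 pairs are required")
  d <- a - b
  obs <- mean(d)

  exhaustive <- 2^n <= nPerm
  S <- if (exhaustive) {
    signMatrixExhaustive(n)
  } else {
    signMatrixRandom(nPerm, n, seed)
  }
  null <- drop(S %*% d) / n
  eps <- 1e-10 * (1 + abs(obs))
  cnt <- switch(side,
    greater = sum(null >= obs - eps),
    less = sum(null <= obs + eps),
    two.sided = sum(abs(null) >= abs(obs) - eps)
  )
  p <- if (exhaustive) cnt / nrow(S) else (1 + cnt) / (1 + nPerm)
  structure(
    list(
      statistic = obs, p = p, nPerm = nrow(S), exhaustive = exhaustive,
      side = side, n = n
    ),
    class = "prosynPermTest"
  )
}

#' @export
print.prosynPermTest <- function(x, ...) {
  cat(sprintf(
    "Paired sign-flip permutation test (%s, n = %d): mean diff = %.4f, p = %.4g (%s, %d permutations)\n",
    x$side, x$n, x$statistic, x$p,
    if (x$exhaustive) "exhaustive" else "random", x$nPerm
  ))
  invisible(x)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Sorts p-values ascending, multiplies the i-th by (m - i + 1), enforces
#' monotonicity and caps at 1 (delegating to [stats::p.adjust()]), after
#' validating the inputs.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @examples
#' holmAdjust(c(0.01, 0.04, 0.03)) # 0.03 0.06 0.06
#' @export
holmAdjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "holm")
}

# Per-permutation studentized means. Under sign flips the per-timepoint sum
# of squares is invariant, so t is a closed form of the flipped mean.
flippedTValues <- function(S, D) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ss <- colSums(D^2)
  varM <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  varM[varM < 1e-24] <- NA
  t <- M / sqrt(varM / n)
  t[is.na(t)] <- 0
  t
}

# Fast max |cluster mass| for one t series (used for the permutation null;
# avoids the data.frame bookkeeping of clusterRuns).
maxClusterMass <- function(t, thresh, side) {
  above <- if (side == "two.sided") abs(t) > thresh else t > thresh
  if (!any(above)) {
    return(0)
  }
  r <- rle(as.vector(above))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- 0
  for (k in which(r$values)) {
    tk <- t[starts[k]:ends[k]]
    if (side == "two.sided") {
      # runs of |t| > thresh can mix signs: split at sign changes
      rs <- rle(sign(tk))
      e2 <- cumsum(rs$lengths)
      s2 <- e2 - rs$lengths + 1L
      for (q in seq_along(rs$values)) m <- max(m, abs(sum(tk[s2[q]:e2[q]])))
    } else {
      m <- max(m, sum(tk))
    }
  }
  m
}

# Maximal runs of supra-threshold timepoints and their masses.
clusterRuns <- function(t, thresh, side) {
  above <- if (side == "two.sided") abs(t) > thresh else t > thresh
  if (!any(above)) {
    return(data.frame(start = integer(), end = integer(), mass = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  # a run of |t| > thresh can mix signs under two.sided; split at sign changes
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    if (side == "two.sided") {
      sgn <- sign(t[idx])
      grp <- cumsum(c(1L, diff(sgn) != 0))
      do.call(rbind, lapply(split(idx, grp), function(ii) {
        data.frame(start = ii[1], end = ii[length(ii)], mass = sum(t[ii]))
      }))
    } else {
      data.frame(start = idx[1], end = idx[length(idx)], mass = sum(t[idx]))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cluster-based permutation test over time
#'
#' One-sample cluster-level test of a subjects-by-timepoints series (e.g.
#' AUC - 0.5, or a condition difference) against zero. Pointwise t values
#' are thresholded at the two-sided t quantile for `clusterAlpha` at
#' `n - 1` degrees of freedom; clusters are maximal runs of adjacent
#' supra-threshold timepoints with mass the sum of t inside; the null is
#' the maximum cluster mass over sign-flip permutations (exhaustive when
#' `2^n <= nPerm`). Zero-variance timepoints yield t = 0 with a warning.
#'
#' @param series numeric matrix, subjects x timepoints.
#' @param times optional timepoint positions in seconds (for reporting).
#' @param nPerm permutation budget (default 2048).
#' @param clusterAlpha cluster-forming alpha (default 0.05, two-sided
#'   quantile).
#' @param side `"greater"` (default) tests positive clusters only;
#'   `"two.sided"` forms clusters of either sign and compares |mass|.
#' @param seed RNG seed for non-exhaustive permutation draws.
#' @return a `"prosynClusterTest"` list: `clusters` (data.frame with
#'   start/end indices, times if given, mass, p), `tValues`, `threshold`,
#'   `nPerm`, `exhaustive`.
#' @export
clusterPermutationTest <- function(series, times = NULL, nPerm = 2048,
                                   clusterAlpha = 0.05,
                                   side = c("greater", "two.sided"), seed = 1) {
  side <- match.arg(side)
  series <- as.matrix(series)
  n <- nrow(series)
  nT <- ncol(series)
  if (n < 2L) stopf("at least 2 subjects are required")
  if (nT < 1L) stopf("at least 1 timepoint is required")
  if (!is.null(times) && length(times) != nT) stopf("'times' must match the timepoint count")

  sdv <- apply(series, 2, sd)
  if (any(sdv < 1e-12)) {
    warning("zero-variance timepoint(s): t treated as 0", call. = FALSE)
  }
  tObs <- drop(flippedTValues(matrix(1, 1, n), series))
  thresh <- qt(1 - clusterAlpha / 2, df = n - 1)
  obs <- clusterRuns(tObs, thresh, side)

  exhaustive <- 2^n <= nPerm
  S <- if (exhaustive) signMatrixExhaustive(n) else signMatrixRandom(nPerm, n, seed)
  Tnull <- flippedTValues(S, series)
  nullMax <- vapply(seq_len(nrow(S)), function(i) {
    maxClusterMass(Tnull[i, ], thresh, side)
  }, numeric(1))

  if (nrow(obs)) {
    obs$p <- vapply(obs$mass, function(m) {
      cnt <- sum(nullMax >= abs(m) - 1e-10)
      if (exhaustive) cnt / length(nullMax) else (1 + cnt) / (1 + length(nullMax))
    }, numeric(1))
    if (!is.null(times)) {
      obs$tStart <- times[obs$start]
      obs$tEnd <- times[obs$end]
    }
    obs <- obs[order(obs$start), , drop = FALSE]
    rownames(obs) <- NULL
  } else {
    obs$p <- numeric(0)
  }
  structure(
    list(
      clusters = obs, tValues = tObs, threshold = thresh, side = side,
      nPerm = nrow(S), exhaustive = exhaustive, times = times
    ),
    class = "prosynClusterTest"
  )
}

#' @export
print.prosynClusterTest <- function(x, ...) {
  cat(sprintf(
    "Cluster permutation test (%s): threshold |t| > %.3f, %d permutations (%s)\n",
    x$side, x$threshold, x$nPerm, if (x$exhaustive) "exhaustive" else "random"
  ))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      loc <- if (!is.null(x$times)) {
        sprintf("[%.3f, %.3f] s", cl$tStart, cl$tEnd)
      } else {
        sprintf("[%d, %d]", cl$start, cl$end)
      }
      cat(sprintf("  cluster %d: %s, mass = %.2f, p = %.4g\n", i, loc, cl$mass, cl$p))
    }
  }
  invisible(x)
}

#' Bayesian population prevalence (MAP and HPDI)
#'
#' Lower-bound prevalence model for the fraction of the population showing
#' a within-subject significant effect: each subject tests significant
#' with probability `theta = alpha + gamma * (1 - alpha)`, where `gamma`
#' is the population prevalence of true effects and `alpha` the
#' within-subject false-positive level. With a uniform prior on `theta`
#' the posterior after observing `k` of `n` significant subjects is
#' `Beta(k + 1, n - k + 1)`; the prevalence MAP is the posterior mode
#' mapped through the model, `max(0, (k/n - alpha) / (1 - alpha))`, and
#' the 95% highest-posterior-density interval is found numerically on the
#' `theta` posterior, mapped to `gamma` and truncated to `[0, 1]`.
#'
#' @param k number of subjects individually significant.
#' @param n number of subjects (`k <= n`).
#' @param alpha within-subject significance level (default 0.05).
#' @param credMass HPDI probability mass (default 0.95).
#' @return a `"prosynPrevalence"` list: `map`, `hpdi` (length-2), `k`,
#'   `n`, `alpha`, `credMass`.
#' @examples
#' prevalenceEstimate(11, 11) # MAP 1.00, HPDI lower ~0.77
#' @export
prevalenceEstimate <- function(k, n, alpha = 0.05, credMass = 0.95) {
  if (!isCount(k) || !isCount(n) || k > n || n < 1L) {
    stopf("'k' and 'n' must be counts with 0 <= k <= n")
  }
  if (!(alpha > 0 && alpha < 1)) stopf("'alpha' must lie in (0, 1)")
  a <- k + 1
  b <- n - k + 1

  hpdTheta <- if (k == n) {
    c(qbeta(1 - credMass, a, b), 1)
  } else if (k == 0) {
    c(0, qbeta(credMass, a, b))
  } else {
    upper <- function(lo) qbeta(pbeta(lo, a, b) + credMass, a, b)
    opt <- optimize(function(lo) upper(lo) - lo,
      lower = 0, upper = qbeta(1 - credMass, a, b), tol = 1e-12
    )
    c(opt$minimum, upper(opt$minimum))
  }

  toGamma <- function(theta) pmin(1, pmax(0, (theta - alpha) / (1 - alpha)))
  structure(
    list(
      map = max(0, (k / n - alpha) / (1 - alpha)),
      hpdi = toGamma(hpdTheta),
      k = k, n = n, alpha = alpha, credMass = credMass
    ),
    class = "prosynPrevalence"
  )
}

#' @export
print.prosynPrevalence <- function(x, ...) {
  cat(sprintf(
    "Population prevalence (k = %d / n = %d, alpha = %.2f): MAP = %.2f, %d%% HPDI: [%.2f %.2f]\n",
    x$k, x$n, x$alpha, x$map, round(100 * x$credMass), x$hpdi[1], x$hpdi[2]
  ))
  invisible(x)
}
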