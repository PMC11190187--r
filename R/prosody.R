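# Two-component gamma mixture for prosodic boundary strength, the
# weak/strong binarization boundary, and the stimulus-level prosody-syntax
# association tests.

# Weighted gamma MLE: shape via Newton iteration on the digamma equation
# log(a) - digamma(a) = log(wmean) - wmeanlog, method-of-moments style start.
gammaMleWeighted <- function(x, w, fallback = list(shape = 1, rate = 1)) {
  W <- sum(w)
  if (W < 1e-10) return(fallback)
  m <- sum(w * x) / W
  ml <- sum(w * log(x)) / W
  s <- log(m) - ml # >= 0 by Jensen; 0 only for degenerate (constant) data
  if (!is.finite(s) || s < 1e-12) {
    return(list(shape = 1e6, rate = 1e6 / m))
  }
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in seq_len(100)) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    aNew <- a - step
    if (aNew <= 0) aNew <- a / 2
    if (abs(aNew - a) < 1e-12 * (1 + a)) {
      a <- aNew
      break
    }
    a <- aNew
  }
  list(shape = a, rate = a / m)
}

mixtureLoglik <- function(x, w, shape, rate) {
  sum(log(w[1] * dgamma(x, shape[1], rate = rate[1]) +
    w[2] * dgamma(x, shape[2], rate = rate[2])))
}

# One EM run from a given split quantile initialization.
emGammaRun <- function(x, splitQ, tol, maxIter) {
  cut <- quantile(x, splitQ, names = FALSE)
  lowIdx <- x <= cut
  if (sum(lowIdx) < 2L || sum(!lowIdx) < 2L) {
    ord <- order(x)
    lowIdx <- seq_along(x) %in% ord[seq_len(max(2L, floor(length(x) / 2)))]
  }
  momFit <- function(xs) {
    m <- mean(xs)
    v <- var(xs)
    if (!is.finite(v) || v <= 0) v <- m^2 / 4
    list(shape = max(m^2 / v, 1e-3), rate = max(m / v, 1e-6))
  }
  f1 <- momFit(x[lowIdx])
  f2 <- momFit(x[!lowIdx])
  w <- c(mean(lowIdx), mean(!lowIdx))
  shape <- c(f1$shape, f2$shape)
  rate <- c(f1$rate, f2$rate)

  trace <- numeric(0)
  llPrev <- -Inf
  converged <- FALSE
  nIter <- 0L
  for (iter in seq_len(maxIter)) {
    nIter <- iter
    d1 <- w[1] * dgamma(x, shape[1], rate = rate[1])
    d2 <- w[2] * dgamma(x, shape[2], rate = rate[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(llPrev) && abs(ll - llPrev) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    llPrev <- ll
    r2 <- d2 / tot
    r1 <- 1 - r2
    w <- c(mean(r1), mean(r2))
    g1 <- gammaMleWeighted(x, r1, fallback = list(shape = shape[1], rate = rate[1]))
    g2 <- gammaMleWeighted(x, r2, fallback = list(shape = shape[2], rate = rate[2]))
    shape <- c(g1$shape, g2$shape)
    rate <- c(g1$rate, g2$rate)
  }
  list(
    w = w, shape = shape, rate = rate, loglik = trace[length(trace)],
    trace = trace, nIter = nIter, converged = converged
  )
}

#' Fit a two-component gamma mixture by EM
#'
#' Expectation-maximization with gamma component densities. The M-step uses
#' the exact weighted gamma MLE (Newton iteration on the digamma equation
#' with a method-of-moments start), so the log-likelihood is non-decreasing
#' across iterations. Restarts are initialized by splitting the sample at
#' jittered quantiles around the median; the restart with the best final
#' log-likelihood is returned. Components are ordered so that component 2
#' has the larger mean, and the weak/strong binarization boundary (the
#' equal-posterior density crossing between the component means) is
#' attached to the fit.
#'
#' @param x positive strength values (length >= 10).
#' @param nRestarts number of jittered-split restarts (default 5).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations per restart (default 500).
#' @param seed optional seed for the restart jitter.
#' @return a [GammaMixtureFit-class]. `boundary` is `NA` (with a warning)
#'   when the fitted components are too similar for a density crossing to
#'   exist between their means.
#' @examples
#' set.seed(1)
#' x <- c(rgamma(500, 1.1, 2.8), rgamma(500, 14, 10.7))
#' fit <- fitGammaMixture(x)
#' mixtureParameters(fit)
#' @export
fitGammaMixture <- function(x, nRestarts = 5, tol = 1e-8, maxIter = 500, seed = NULL) {
  if (!is.numeric(x) || any(!is.finite(x))) stopf("strengths must be finite numerics")
  if (any(x <= 0)) {
    stopf("all strengths must be strictly positive; remove zero-strength tokens first")
  }
  if (length(x) < 10L) stopf("at least 10 values are required to fit the mixture")

  splits <- 0.5
  if (nRestarts > 1L) {
    jitter <- withSeed(
      if (is.null(seed)) 20240101 else seed,
      runif(nRestarts - 1L, -0.15, 0.15)
    )
    splits <- c(0.5, 0.5 + jitter)
  }
  runs <- lapply(splits, function(q) emGammaRun(x, q, tol, maxIter))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]

  ord <- order(best$shape / best$rate)
  w <- best$w[ord]
  shape <- best$shape[ord]
  rate <- best$rate[ord]
  boundary <- tryCatch(
    gammaCrossing(w, shape, rate),
    error = function(e) {
      warning("degenerate fit: ", conditionMessage(e), call. = FALSE)
      NA_real_
    }
  )
  if (!best$converged) {
    warning("EM did not converge within ", maxIter, " iterations; best iterate returned",
      call. = FALSE
    )
  }
  new("GammaMixtureFit",
    w = w, shape = shape, rate = rate, loglik = best$loglik,
    boundary = boundary, nIter = best$nIter, converged = best$converged,
    loglikTrace = best$trace
  )
}

# Bisection for the weighted-density crossing between the component means.
gammaCrossing <- function(w, shape, rate, tol = 1e-8) {
  mu <- shape / rate
  if (abs(mu[2] - mu[1]) < 1e-10) {
    stopf("component means coincide; no binarization boundary exists")
  }
  g <- function(z) {
    w[1] * dgamma(z, shape[1], rate = rate[1]) -
      w[2] * dgamma(z, shape[2], rate = rate[2])
  }
  lo <- min(mu)
  hi <- max(mu)
  glo <- g(lo)
  ghi <- g(hi)
  if (glo == 0) return(lo)
  if (ghi == 0) return(hi)
  if (sign(glo) == sign(ghi)) {
    stopf("no density crossing between the component means (degenerate fit)")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) return(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid
      glo <- gm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' @describeIn GammaMixtureFit-class Recompute the weak/strong binarization
#'   boundary of a fit: the strength between the two component means at
#'   which the weighted component densities are equal (bisection to 1e-8),
#'   i.e. the point of 0.5/0.5 posterior membership. Errors for a
#'   degenerate fit with no crossing.
#' @param ... unused.
#' @export
setMethod("mixtureBoundary", "GammaMixtureFit", function(fit, ...) {
  gammaCrossing(fit@w, fit@shape, fit@rate)
})

#' Posterior membership probability of the strong component
#'
#' @param fit a [GammaMixtureFit-class].
#' @param x strength values.
#' @return P(component 2 | x) for each value.
#' @export
posteriorStrong <- function(fit, x) {
  d1 <- fit@w[1] * dgamma(x, fit@shape[1], rate = fit@rate[1])
  d2 <- fit@w[2] * dgamma(x, fit@shape[2], rate = fit@rate[2])
  d2 / (d1 + d2)
}

#' Binarize strengths at the mixture boundary
#'
#' Strong iff strength exceeds the boundary; a value exactly at the
#' boundary is classified weak (the conservative tie-break: the neutral
#' pool grows). Zero strengths are an error because zero-strength tokens
#' must be excluded before prosodic modeling.
#'
#' @param x positive strength values.
#' @param boundary the binarization boundary (e.g. `mixtureBoundary(fit)`).
#' @return a factor with levels `c("weak", "strong")`.
#' @examples
#' classifyStrength(c(0.5, 2), boundary = 1.01)
#' @export
classifyStrength <- function(x, boundary) {
  stopifnot(isPositiveScalar(boundary))
  if (any(x <= 0)) {
    stopf(paste(
      "strengths must be strictly positive: zero-strength tokens carry no",
      "spectral content and must be excluded by the filtering rule before",
      "classification"
    ))
  }
  factor(ifelse(x > boundary, "strong", "weak"), levels = c("weak", "strong"))
}

#' Test the stimulus-level prosody-syntax association
#'
#' Two complementary models of the association between binarized prosodic
#' boundary strength and the presence of a closing phrase boundary:
#' (a) a binomial-family GLM (logit link) of the closing label on the
#' prosody class, reporting the coefficient z and p; and (b) a
#' Gamma-family GLM with inverse link of the continuous strength on the
#' closing label, reporting the coefficient t and p. The 2x2 contingency
#' table and per-class strength means are attached. Note the inverse link
#' reverses the coefficient sign relative to the mean difference:
#' `strengthDirection` reports the sign of
#' mean(strength | closing) - mean(strength | non-closing).
#'
#' @param table a word table with columns `strength` (positive) and
#'   `closing` (logical).
#' @param labels weak/strong prosody labels aligned with `table` (e.g. from
#'   [classifyStrength()]).
#' @return an object of class `"prosynAssociation"`.
#' @export
testAssociation <- function(table, labels) {
  if (!all(c("strength", "closing") %in% names(table))) {
    stopf("table must have 'strength' and 'closing' columns")
  }
  if (NROW(table) != length(labels)) stopf("labels must align with the table rows")
  labels <- factor(labels, levels = c("weak", "strong"))
  closing <- as.logical(table$closing)
  if (length(unique(labels[!is.na(labels)])) < 2L) stopf("prosody labels must have two levels")
  if (length(unique(closing)) < 2L) stopf("closing labels must have two levels")
  if (any(table$strength <= 0)) stopf("strengths must be strictly positive")

  binFit <- glm(closing ~ labels, family = binomial())
  binCoef <- summary(binFit)$coefficients["labelsstrong", ]

  gamFit <- glm(table$strength ~ closing, family = Gamma(link = "inverse"))
  gamCoef <- summary(gamFit)$coefficients["closingTRUE", ]

  res <- list(
    binomialZ = unname(binCoef["z value"]),
    binomialP = unname(binCoef["Pr(>|z|)"]),
    gammaGlmT = unname(gamCoef["t value"]),
    gammaGlmP = unname(gamCoef["Pr(>|t|)"]),
    contingency = base::table(prosody = labels, closing = closing),
    meanStrength = tapply(table$strength, closing, mean),
    strengthDirection = sign(
      mean(table$strength[closing]) - mean(table$strength[!closing])
    )
  )
  class(res) <- "prosynAssociation"
  res
}

#' @export
print.prosynAssociation <- function(x, ...) {
  cat("Prosody-syntax association\n")
  cat(sprintf(
    "  binomial GLM (closing ~ prosody class): z = %.2f, p = %.3g\n",
    x$binomialZ, x$binomialP
  ))
  cat(sprintf(
    "  Gamma GLM, inverse link (strength ~ closing): t = %.2f, p = %.3g\n",
    x$gammaGlmT, x$gammaGlmP
  ))
  cat(sprintf(
    "  strength is %s for closing-boundary words\n",
    if (x$strengthDirection > 0) "greater" else "smaller"
  ))
  cat("  contingency (prosody x closing):\n")
  print(x$contingency)
  invisible(x)
}
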