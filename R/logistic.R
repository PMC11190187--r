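# L2-regularized logistic regression used by the decoders.
#
# Objective (scikit-learn style "C" parameterization):
#   J(w, b) = sum_i log(1 + exp(-(2 y_i - 1) * (x_i' w + b))) + ||w||^2 / (2 C)
# with the intercept unpenalized. Newton-IRLS with step halving is used for
# moderate feature counts; wide problems (many features, as in whole-window
# MVPA) use limited-memory BFGS on the same objective.

logisticObjective <- function(wb, X, y, C) {
  p <- ncol(X)
  w <- wb[seq_len(p)]
  b <- wb[p + 1L]
  eta <- drop(X %*% w) + b
  # log(1 + exp(eta)) - y * eta, computed stably
  lse <- ifelse(eta > 30, eta, log1p(exp(eta)))
  sum(lse - y * eta) + sum(w^2) / (2 * C)
}

logisticGradient <- function(wb, X, y, C) {
  p <- ncol(X)
  w <- wb[seq_len(p)]
  b <- wb[p + 1L]
  mu <- plogis(drop(X %*% w) + b)
  r <- mu - y
  c(drop(crossprod(X, r)) + w / C, sum(r))
}

#' Fit an L2-penalized logistic classifier
#'
#' Minimizes the logistic loss plus `||w||^2 / (2C)` with an unpenalized
#' intercept -- the usual `C` parameterization of regularized linear
#' decoders (larger `C`, weaker regularization). Newton iterations with
#' step halving are used up to 700 features; wider problems switch to
#' L-BFGS on the identical objective. Deterministic given the data.
#'
#' @param X numeric feature matrix (observations x features).
#' @param y binary labels (logical or 0/1; both classes must be present).
#' @param C regularization parameter (> 0).
#' @param tol relative objective convergence tolerance (default 1e-8).
#' @param maxIter Newton iteration cap (default 100).
#' @param init optional warm-start `list(weights =, intercept =)`.
#' @return a `"prosynLogistic"` list with `weights`, `intercept`,
#'   `objective`, `converged`.
#' @export
fitLogistic <- function(X, y, C = 1, tol = 1e-8, maxIter = 100, init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(as.logical(y))
  if (anyNA(y)) stopf("labels must be binary with no NA")
  if (length(unique(y)) < 2L) stopf("both classes must be present to fit the decoder")
  if (!isPositiveScalar(C)) stopf("'C' must be a positive scalar")
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stopf("labels must align with the rows of 'X'")

  wb <- if (!is.null(init)) c(init$weights, init$intercept) else numeric(p + 1L)

  if (p <= 700L) {
    obj <- logisticObjective(wb, X, y, C)
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
      w <- wb[seq_len(p)]
      b <- wb[p + 1L]
      eta <- drop(X %*% w) + b
      mu <- plogis(eta)
      grad <- c(drop(crossprod(X, mu - y)) + w / C, sum(mu - y))
      wt <- pmax(mu * (1 - mu), 1e-10)
      Xa <- cbind(X, 1)
      H <- crossprod(Xa, Xa * wt)
      diag(H)[seq_len(p)] <- diag(H)[seq_len(p)] + 1 / C
      delta <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
      step <- 1
      repeat {
        cand <- wb - step * delta
        objNew <- logisticObjective(cand, X, y, C)
        if (objNew <= obj + 1e-12 || step < 1e-8) break
        step <- step / 2
      }
      if (objNew > obj) break # no descent possible: numerically converged
      relChange <- (obj - objNew) / (1 + abs(obj))
      wb <- cand
      obj <- objNew
      if (relChange < tol) {
        converged <- TRUE
        break
      }
    }
  } else {
    fit <- optim(wb, logisticObjective, logisticGradient,
      X = X, y = y, C = C,
      method = "L-BFGS-B",
      control = list(maxit = 1000, factr = 1e4)
    )
    wb <- fit$par
    obj <- fit$value
    converged <- fit$convergence == 0L
  }

  structure(
    list(
      weights = wb[seq_len(p)], intercept = wb[p + 1L],
      objective = obj, converged = converged, C = C
    ),
    class = "prosynLogistic"
  )
}

#' Linear decision scores of a fitted logistic classifier
#'
#' @param model a `"prosynLogistic"` fit.
#' @param X feature matrix.
#' @return numeric scores (higher = more likely closing-boundary).
#' @export
predictLogistic <- function(model, X) {
  drop(as.matrix(X) %*% model$weights) + model$intercept
}

#' @export
print.prosynLogistic <- function(x, ...) {
  cat(sprintf(
    "L2-logistic fit: %d feature(s), C = %g, |w| = %.4g, intercept = %.4g, converged: %s\n",
    length(x$weights), x$C, sqrt(sum(x$weights^2)), x$intercept, x$converged
  ))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted 1/2 (Mann-Whitney formulation via
#' mid-ranks).
#'
#' @param scores numeric classifier scores.
#' @param y binary labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @examples
#' computeAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)) # 0.75
#' @export
computeAuc <- function(scores, y) {
  y <- as.logical(y)
  if (length(scores) != length(y)) stopf("scores and labels must be aligned")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
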