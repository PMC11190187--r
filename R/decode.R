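# Whole-window MVPA and per-timepoint temporal decoding with
# train-on-neutral, test-on-three-conditions generalization.

# Flatten an EpochSet to an (epochs) x (components * samples) feature matrix.
featureMatrix <- function(es) {
  d <- dim(es@data)
  matrix(es@data, nrow = d[1])
}

zScoreStats <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

zScoreApply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

checkTestsList <- function(tests) {
  if (!is.list(tests) || is.null(names(tests)) || any(!nzchar(names(tests)))) {
    stopf("'tests' must be a named list of EpochSet objects")
  }
  for (es in tests) stopifnot(is(es, "EpochSet"))
  invisible(tests)
}

foldAssignment <- function(n, nFolds, seed) {
  withSeed(seed, sample(rep_len(seq_len(nFolds), n)))
}

#' Whole-window MVPA decoding with cross-condition generalization
#'
#' Features are the concatenated component-by-sample amplitudes in the
#' window, z-scored by training statistics. The training pool is split
#' into shuffled folds; per fold, a logistic classifier (default C = 1) is
#' fitted on the remaining nine tenths and scored by AUC on each fixed test
#' set (the held-out tenth itself is not scored -- the test sets are fixed
#' and disjoint from the pool). Per-condition AUCs are averaged over
#' folds. Standardization uses the per-fold training data only, so no
#' test-set information enters training.
#'
#' @param train training-pool [EpochSet-class] (class-balanced, weak
#'   prosody).
#' @param tests named list of test [EpochSet-class] objects (typically
#'   `neutral`, `coherent`, `incoherent`).
#' @param window half-open time window `c(t0, t1)` in seconds (must lie
#'   within the epoch range).
#' @param C logistic regularization parameter (default 1).
#' @param nFolds folds of the randomized cross-validation (default 10).
#' @param seed RNG seed for the fold shuffle.
#' @return a `"prosynMvpa"` object: `aucs` (long data.frame: fold,
#'   condition, auc), `meanAuc` (named per-condition means), plus the
#'   settings.
#' @export
mvpaDecode <- function(train, tests, window = c(0, 0.4), C = 1, nFolds = 10, seed = 1) {
  stopifnot(is(train, "EpochSet"))
  checkTestsList(tests)
  if (length(window) != 2L) stopf("'window' must be c(t0, t1)")
  tr <- windowEpochs(train, window[1], window[2])
  te <- lapply(tests, windowEpochs, t0 = window[1], t1 = window[2])
  y <- epochLabels(tr)
  if (anyNA(y)) stopf("training labels must be defined")
  if (min(sum(y), sum(!y)) < nFolds) stopf("too few training epochs per class for %d folds", nFolds)
  if (abs(sum(y) - sum(!y)) > 0L) {
    warning("training pool is not class-balanced", call. = FALSE)
  }

  Xtr <- featureMatrix(tr)
  Xte <- lapply(te, featureMatrix)
  yte <- lapply(te, epochLabels)
  folds <- foldAssignment(nrow(Xtr), nFolds, seed)

  rows <- list()
  for (f in seq_len(nFolds)) {
    fitIdx <- which(folds != f)
    st <- zScoreStats(Xtr[fitIdx, , drop = FALSE])
    model <- fitLogistic(zScoreApply(Xtr[fitIdx, , drop = FALSE], st), y[fitIdx], C = C)
    for (cond in names(tests)) {
      sc <- predictLogistic(model, zScoreApply(Xte[[cond]], st))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, condition = cond, auc = computeAuc(sc, yte[[cond]]),
        stringsAsFactors = FALSE
      )
    }
  }
  aucs <- do.call(rbind, rows)
  meanAuc <- tapply(aucs$auc, aucs$condition, mean)[names(tests)]
  structure(
    list(
      aucs = aucs, meanAuc = meanAuc, C = C, window = window,
      nFolds = nFolds, seed = seed
    ),
    class = "prosynMvpa"
  )
}

#' @export
print.prosynMvpa <- function(x, ...) {
  cat(sprintf(
    "MVPA decoding, window [%g, %g) s, C = %g, %d folds\n",
    x$window[1], x$window[2], x$C, x$nFolds
  ))
  for (cond in names(x$meanAuc)) {
    cat(sprintf("  %-11s mean AUC = %.3f\n", paste0(cond, ":"), x$meanAuc[[cond]]))
  }
  invisible(x)
}

#' Per-timepoint temporal decoding with nested C selection
#'
#' One regularized logistic classifier per timepoint, with features the
#' component amplitudes at that sample. The regularization parameter is
#' selected per timepoint by nested cross-validation on the training pool
#' (default fivefold) over a log-spaced grid (default one value per decade
#' from 1e-5 to 1e5), maximizing the mean inner AUC with ties broken
#' toward the smallest C (strongest regularization). The winning C is
#' refitted on the full training pool and scored on each test set.
#'
#' @param train training-pool [EpochSet-class].
#' @param tests named list of test [EpochSet-class] objects.
#' @param Cgrid regularization grid (default `10^(-5:5)`).
#' @param innerFolds inner folds for C selection (default 5).
#' @param seed RNG seed for the inner fold shuffle.
#' @return a `"prosynTemporal"` object: `aucs` (long data.frame: time,
#'   condition, auc), `selectedC` (per timepoint), `times`.
#' @export
temporalDecode <- function(train, tests, Cgrid = 10^seq(-5, 5), innerFolds = 5, seed = 1) {
  stopifnot(is(train, "EpochSet"))
  checkTestsList(tests)
  Cgrid <- sort(Cgrid)
  y <- epochLabels(train)
  if (anyNA(y)) stopf("training labels must be defined")
  if (min(sum(y), sum(!y)) < innerFolds) {
    stopf("too few training epochs per class for %d inner folds", innerFolds)
  }
  times <- epochTimes(train)
  nT <- length(times)
  folds <- foldAssignment(nEpochs(train), innerFolds, seed)

  teDat <- lapply(tests, function(es) {
    if (length(epochTimes(es)) != nT || max(abs(epochTimes(es) - times)) > 1e-9) {
      stopf("test epochs must share the training time axis")
    }
    es@data
  })
  yte <- lapply(tests, epochLabels)

  selectedC <- numeric(nT)
  rows <- vector("list", nT * length(tests))
  ri <- 0L
  for (j in seq_len(nT)) {
    Xj <- train@data[, , j, drop = TRUE]
    if (is.null(dim(Xj))) Xj <- matrix(Xj, ncol = dim(train@data)[2])
    innerAuc <- matrix(NA_real_, innerFolds, length(Cgrid))
    for (f in seq_len(innerFolds)) {
      fitIdx <- which(folds != f)
      valIdx <- which(folds == f)
      if (length(unique(y[valIdx])) < 2L || length(unique(y[fitIdx])) < 2L) next
      st <- zScoreStats(Xj[fitIdx, , drop = FALSE])
      Xfit <- zScoreApply(Xj[fitIdx, , drop = FALSE], st)
      Xval <- zScoreApply(Xj[valIdx, , drop = FALSE], st)
      model <- NULL
      for (ci in seq_along(Cgrid)) {
        model <- fitLogistic(Xfit, y[fitIdx],
          C = Cgrid[ci], tol = 1e-6,
          init = model
        )
        innerAuc[f, ci] <- computeAuc(predictLogistic(model, Xval), y[valIdx])
      }
    }
    meanInner <- colMeans(innerAuc, na.rm = TRUE)
    best <- which(meanInner >= max(meanInner) - 1e-12)[1] # tie -> smallest C
    selectedC[j] <- Cgrid[best]

    st <- zScoreStats(Xj)
    model <- fitLogistic(zScoreApply(Xj, st), y, C = Cgrid[best], tol = 1e-6)
    for (cond in names(tests)) {
      Xt <- teDat[[cond]][, , j, drop = TRUE]
      if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = dim(train@data)[2])
      sc <- predictLogistic(model, zScoreApply(Xt, st))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        time = times[j], condition = cond, auc = computeAuc(sc, yte[[cond]]),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      aucs = do.call(rbind, rows[seq_len(ri)]), selectedC = selectedC,
      times = times, Cgrid = Cgrid, innerFolds = innerFolds, seed = seed
    ),
    class = "prosynTemporal"
  )
}

#' @export
print.prosynTemporal <- function(x, ...) {
  conds <- unique(x$aucs$condition)
  cat(sprintf(
    "Temporal decoding over %d timepoint(s) in [%.3f, %.3f] s\n",
    length(x$times), min(x$times), max(x$times)
  ))
  for (cond in conds) {
    a <- x$aucs[x$aucs$condition == cond, ]
    pk <- a$time[which.max(a$auc)]
    cat(sprintf(
      "  %-11s max AUC = %.3f at %+.3f s\n", paste0(cond, ":"), max(a$auc), pk
    ))
  }
  invisible(x)
}

#' AUC matrix helper for group statistics
#'
#' Stacks per-subject temporal AUC series for one condition into a
#' subjects x timepoints matrix, as consumed by
#' [clusterPermutationTest()].
#'
#' @param results list of `"prosynTemporal"` objects, one per subject.
#' @param condition condition name to extract.
#' @return numeric matrix, subjects x timepoints.
#' @export
temporalAucMatrix <- function(results, condition) {
  rows <- lapply(results, function(r) {
    a <- r$aucs[r$aucs$condition == condition, ]
    a$auc[order(a$time)]
  })
  do.call(rbind, rows)
}
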