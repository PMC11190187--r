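# Logistic decoder, AUC, MVPA and temporal decoding.

test_that("AUC matches hand examples and the pairwise-enumeration oracle", {
  expect_equal(computeAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(computeAuc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(computeAuc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(computeAuc(1:3, c(1, 1, 1)), "both classes")

  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    sc <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
    expect_equal(computeAuc(sc, y), aucPairwise(sc, y))
  }
})

test_that("the penalized logistic fit behaves like its objective demands", {
  # separable 1-D data: positive weight
  X <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fitLogistic(X, y, C = 1)
  expect_gt(fit$weights[1], 0)

  # ||w|| is non-decreasing in C on fixed data
  set.seed(66)
  X2 <- matrix(rnorm(200), 50, 4)
  y2 <- rbinom(50, 1, plogis(X2 %*% c(1, -1, 0.5, 0)))
  norms <- vapply(10^seq(-3, 3), function(C) {
    sqrt(sum(fitLogistic(X2, y2, C = C)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-6))

  # class-symmetric data: intercept ~ 0
  Xs <- rbind(X2, -X2)
  ys <- c(rep(1, 50), rep(0, 50))
  expect_lt(abs(fitLogistic(Xs, ys, C = 1)$intercept), 1e-4)

  expect_error(fitLogistic(X, rep(1, 6)), "both classes")
  expect_error(fitLogistic(X, y, C = 0), "positive")
})

test_that("narrow and wide solver paths agree on the same objective", {
  set.seed(77)
  n <- 40
  p <- 750 # wide: L-BFGS path
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.5)
  y[1:2] <- c(0, 1)
  wide <- fitLogistic(X, y, C = 0.1)
  # same data through the Newton path on a feature subset where both run
  Xn <- X[, 1:100]
  narrow <- fitLogistic(Xn, y, C = 0.1)
  obj <- function(fit, X) {
    eta <- X %*% fit$weights + fit$intercept
    sum(log1p(exp(eta)) - y * eta) + sum(fit$weights^2) / (2 * 0.1)
  }
  # L-BFGS achieves the Newton objective to high relative accuracy
  wideRef <- fitLogistic(X[, 1:100], y, C = 0.1)
  expect_lt(abs(obj(narrow, Xn) - obj(wideRef, Xn)) / abs(obj(narrow, Xn)), 1e-8)
  expect_true(wide$converged)
})

test_that("glmnet ridge-logistic cross-checks the decoder weights", {
  skip_if_not_installed("glmnet")
  set.seed(88)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0, 0.3, 0)))
  C <- 0.5
  ours <- fitLogistic(X, y, C = C)
  # glmnet ridge: (1/n) loglik + lambda/2 ||w||^2  =>  lambda = 1/(n C)
  gn <- glmnet::glmnet(X, y,
    family = "binomial", alpha = 0, lambda = 1 / (n * C),
    standardize = FALSE, thresh = 1e-12
  )
  expect_equal(ours$weights, as.numeric(gn$beta), tolerance = 1e-3)
  expect_equal(ours$intercept, as.numeric(gn$a0), tolerance = 1e-3)
})

test_that("MVPA decoding recovers the planted coherence ordering on a small cohort", {
  sc <- smallLabeledCohort(nSubjects = 3, nWords = 600, seed = 27)
  aucs <- sapply(seq_along(sc$cohort), function(i) {
    sub <- sc$cohort[[i]]
    prep <- prepareSubject(sub$table, sub$recording,
      splitSeed = 100 + i, balanceSeed = 200 + i
    )
    mvpaDecode(prep$train, prep$tests, window = c(0, 0.4), seed = 300 + i)$meanAuc
  })
  groupMean <- rowMeans(aucs)
  expect_gt(groupMean["coherent"], groupMean["incoherent"])
  expect_gt(groupMean["coherent"], 0.55) # well above chance with default gains
})

test_that("label-shuffled training yields chance-level AUC", {
  sc <- smallLabeledCohort(nSubjects = 1, nWords = 600, seed = 29)
  sub <- sc$cohort[[1]]
  prep <- prepareSubject(sub$table, sub$recording, splitSeed = 1, balanceSeed = 2)
  trainPerm <- permuteEpochLabels(prep$train, seed = 3)
  m <- mvpaDecode(trainPerm, prep$tests, window = c(0, 0.4), seed = 4)
  expect_true(all(m$meanAuc > 0.4 & m$meanAuc < 0.6))
})

test_that("temporal decoding selects C by nested CV and scores every timepoint", {
  sc <- smallLabeledCohort(nSubjects = 1, nWords = 400, seed = 33, nChannels = 12)
  sub <- sc$cohort[[1]]
  prep <- prepareSubject(sub$table, sub$recording,
    tmin = -0.1, tmax = 0.3,
    splitSeed = 1, balanceSeed = 2
  )
  td <- temporalDecode(prep$train, prep$tests, Cgrid = 10^seq(-3, 3), seed = 5)
  nT <- length(epochTimes(prep$train))
  expect_equal(length(td$selectedC), nT)
  expect_equal(nrow(td$aucs), nT * 3L)
  expect_true(all(td$aucs$auc >= 0 & td$aucs$auc <= 1))
  expect_true(all(td$selectedC %in% 10^seq(-3, 3)))
})

test_that("inner CV prefers weaker regularization for separable than for null data", {
  set.seed(99)
  n <- 120
  p <- 6
  mkEpochs <- function(signal) {
    y <- rep(c(TRUE, FALSE), n / 2)
    arr <- array(rnorm(n * p * 3), dim = c(n, p, 3))
    arr[, 1, 2] <- arr[, 1, 2] + signal * ifelse(y, 3, -3)
    new("EpochSet",
      data = arr, times = (0:2) / 100, tokenIds = seq_len(n),
      labels = y, fs = 100
    )
  }
  sep <- mkEpochs(1)
  nul <- mkEpochs(0)
  tests <- list(t = sep)
  tdSep <- temporalDecode(sep, list(t = sep), Cgrid = 10^seq(-5, 5), seed = 7)
  tdNul <- temporalDecode(nul, list(t = nul), Cgrid = 10^seq(-5, 5), seed = 7)
  # at the informative timepoint, selected C for separable data is at least
  # the null selection (ties in the null go to the smallest C)
  expect_gte(tdSep$selectedC[2], tdNul$selectedC[2])
})

test_that("no test-set statistics enter training or standardization", {
  sc <- smallLabeledCohort(nSubjects = 1, nWords = 400, seed = 37, nChannels = 8)
  sub <- sc$cohort[[1]]
  prep <- prepareSubject(sub$table, sub$recording, splitSeed = 1, balanceSeed = 2)
  m1 <- mvpaDecode(prep$train, prep$tests, window = c(0, 0.4), seed = 6)
  # rescaling one test set must leave the other conditions' AUCs untouched
  testsMod <- prep$tests
  testsMod$incoherent@data <- testsMod$incoherent@data * 50
  m2 <- mvpaDecode(prep$train, testsMod, window = c(0, 0.4), seed = 6)
  expect_equal(m1$meanAuc[c("neutral", "coherent")], m2$meanAuc[c("neutral", "coherent")])
  # monotone rescaling of test features does not change ranks per fold model,
  # but z-scoring uses training stats only, so incoherent AUC is unchanged too
  expect_equal(m1$meanAuc[["incoherent"]], m2$meanAuc[["incoherent"]])
})
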