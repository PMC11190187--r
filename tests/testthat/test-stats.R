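# Permutation tests, Holm correction, cluster inference, prevalence.

test_that("the paired sign-flip test enumerates exhaustively and matches hand counts", {
  # diffs 1, 2, 3: only the all-positive flip reaches the observed mean
  res <- pairedPermutationTest(c(1, 2, 3), 0, side = "greater")
  expect_true(res$exhaustive)
  expect_equal(res$nPerm, 8L)
  expect_equal(res$p, 1 / 8)

  # all-zero differences: p = 1
  expect_equal(pairedPermutationTest(rep(0.5, 6), 0.5)$p, 1)

  # n = 11 with the default budget: exhaustive over 2^11 = 2048 flips
  set.seed(1)
  res11 <- pairedPermutationTest(runif(11, 0.5, 0.7), 0.5)
  expect_true(res11$exhaustive)
  expect_equal(res11$nPerm, 2048L)

  expect_error(pairedPermutationTest(1:3, 1:4), "equal length")
})

test_that("exhaustive p matches direct enumeration and random draws converge to it", {
  set.seed(2)
  d <- rnorm(8, mean = 0.3)
  res <- pairedPermutationTest(d, 0, side = "greater")
  # direct enumeration oracle
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  nullStats <- signs %*% d / n
  expect_equal(res$p, mean(nullStats >= mean(d) - 1e-12))

  # random permutations approach the exhaustive value
  resRand <- pairedPermutationTest(d, 0, nPerm = 255, side = "greater", seed = 5)
  expect_false(resRand$exhaustive)
  expect_lt(abs(resRand$p - res$p), 0.1)

  # two-sided agrees with |null| enumeration
  res2 <- pairedPermutationTest(d, 0, side = "two.sided")
  expect_equal(res2$p, mean(abs(nullStats) >= abs(mean(d)) - 1e-12))
})

test_that("Holm adjustment matches the hand-computed step-down example", {
  expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmAdjust(0.2), 0.2)
  set.seed(3)
  p <- runif(10)
  adj <- holmAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # significance ordering is never reversed
  expect_identical(order(adj, p), order(p))
  expect_error(holmAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a single-timepoint cluster test reduces to the pointwise permutation test", {
  set.seed(4)
  x <- matrix(rnorm(9, mean = 1.2), ncol = 1)
  ct <- clusterPermutationTest(x, seed = 6)
  expect_equal(nrow(ct$clusters), 1L)
  # pointwise test on the same values: under sign flips the t statistic is
  # monotone in the flipped mean, so the mean-based permutation p is equal
  pt <- pairedPermutationTest(drop(x), 0, side = "greater")
  expect_equal(ct$clusters$p, pt$p)
})

test_that("cluster inference recovers a planted window and respects exhaustiveness", {
  set.seed(7)
  n <- 11
  nT <- 60
  times <- seq(-0.4, 0.79, length.out = nT)
  series <- matrix(rnorm(n * nT, 0, 0.04), n, nT)
  plant <- times >= 0 & times <= 0.2
  series[, plant] <- series[, plant] + 0.12
  ct <- clusterPermutationTest(series, times = times)
  expect_true(ct$exhaustive)
  expect_equal(ct$nPerm, 2048L)
  sig <- ct$clusters[ct$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1L)
  # a significant cluster overlaps the planted window
  expect_true(any(sig$tStart <= 0.2 & sig$tEnd >= 0))

  # degenerate zero-variance timepoint: t treated as 0 with a warning
  series0 <- series
  series0[, 3] <- 1
  expect_warning(ct0 <- clusterPermutationTest(series0, times = times), "zero-variance")
  expect_equal(ct0$tValues[3], 0)
})

test_that("prevalence closed forms match the model", {
  # all subjects significant
  p11 <- prevalenceEstimate(11, 11, alpha = 0.05)
  expect_equal(p11$map, 1)
  expect_equal(p11$hpdi[1], (0.05^(1 / 12) - 0.05) / 0.95, tolerance = 1e-8)
  expect_equal(round(p11$hpdi[1], 2), 0.77)
  expect_equal(p11$hpdi[2], 1)

  # no subject significant: MAP truncates at zero
  expect_equal(prevalenceEstimate(0, 11)$map, 0)
  expect_equal(prevalenceEstimate(0, 11)$hpdi[1], 0)

  # intermediate count: closed-form MAP
  p7 <- prevalenceEstimate(7, 11, alpha = 0.05)
  expect_equal(p7$map, (7 / 11 - 0.05) / 0.95, tolerance = 1e-12)
  expect_equal(round(p7$map, 2), 0.62)

  expect_error(prevalenceEstimate(12, 11), "k")
  expect_error(prevalenceEstimate(3, 11, alpha = 0), "alpha")
})

test_that("prevalence MAP and HPDI obey the model's monotonicity and coverage", {
  maps <- vapply(0:11, function(k) prevalenceEstimate(k, 11)$map, numeric(1))
  expect_true(all(diff(maps) >= 0))

  byAlpha <- vapply(
    c(0.01, 0.05, 0.1, 0.2),
    function(a) prevalenceEstimate(8, 11, alpha = a)$map, numeric(1)
  )
  expect_true(all(diff(byAlpha) <= 0))

  for (k in 0:11) {
    pr <- prevalenceEstimate(k, 11)
    expect_lte(pr$hpdi[1], pr$map)
    expect_gte(pr$hpdi[2], pr$map)
    expect_true(all(pr$hpdi >= 0 & pr$hpdi <= 1))
  }
  # on the untruncated theta scale the interval carries exactly 95% mass
  for (k in c(3, 7, 11)) {
    pr <- prevalenceEstimate(k, 11)
    th <- pr$hpdi * 0.95 + 0.05
    mass <- pbeta(th[2], k + 1, 11 - k + 1) - pbeta(th[1], k + 1, 11 - k + 1)
    expect_equal(mass, 0.95, tolerance = 1e-6)
  }
})
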