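# Gamma-mixture EM, binarization boundary and association tests.

test_that("EM input validation and degenerate one-component data behave", {
  expect_error(fitGammaMixture(c(-1, rep(1, 20))), "positive")
  expect_error(fitGammaMixture(rep(1.5, 5)), "at least 10")

  set.seed(3)
  x <- rgamma(2000, shape = 2, rate = 1)
  fit <- fitGammaMixture(x, seed = 1)
  # one-component data: the second component buys essentially no likelihood
  # over the single-gamma MLE (independent oracle)
  oneComp <- MASS::fitdistr(x, "gamma")
  expect_lt(abs(fit@loglik - oneComp$loglik), 3)
  # EM monotonicity, asserted on the whole trace
  expect_true(all(diff(fit@loglikTrace) > -1e-6 * (1 + abs(fit@loglikTrace[-1]))))
})

test_that("fitted loglik dominates the generating parameters (MLE oracle)", {
  set.seed(8)
  n <- 4000
  comp <- runif(n) < 0.5
  x <- ifelse(comp, rgamma(n, 14, rate = 10.7), rgamma(n, 1.1, rate = 2.8))
  fit <- fitGammaMixture(x, seed = 2)
  llTrue <- sum(log(0.5 * dgamma(x, 1.1, rate = 2.8) + 0.5 * dgamma(x, 14, rate = 10.7)))
  expect_gte(fit@loglik, llTrue)
})

test_that("the boundary is the equal-posterior density crossing between the means", {
  # the printed stimulus components at equal weights
  w <- c(0.5, 0.5)
  shape <- c(1.1, 14)
  rate <- c(2.8, 10.7)
  fit <- new("GammaMixtureFit",
    w = w, shape = shape, rate = rate, loglik = 0,
    boundary = NA_real_, nIter = 1L, converged = TRUE, loglikTrace = numeric(0)
  )
  b <- mixtureBoundary(fit)

  # dense-grid oracle for the density crossing
  grid <- seq(shape[1] / rate[1], shape[2] / rate[2], length.out = 2e5)
  f <- abs(w[1] * dgamma(grid, shape[1], rate = rate[1]) -
    w[2] * dgamma(grid, shape[2], rate = rate[2]))
  expect_lt(abs(b - grid[which.min(f)]), 1e-5)

  # posterior membership at the boundary is 0.5/0.5
  expect_lt(abs(posteriorStrong(fit, b) - 0.5), 1e-6)

  # boundary lies strictly between the component means
  expect_gt(b, shape[1] / rate[1])
  expect_lt(b, shape[2] / rate[2])

  # identical components: no boundary exists
  bad <- new("GammaMixtureFit",
    w = w, shape = c(2, 2), rate = c(1, 1), loglik = 0,
    boundary = NA_real_, nIter = 1L, converged = TRUE, loglikTrace = numeric(0)
  )
  expect_error(mixtureBoundary(bad), "boundary|crossing")
})

test_that("strength binarization applies the boundary with a weak tie-break", {
  lab <- classifyStrength(c(0.5, 2.0), boundary = 1.01)
  expect_equal(as.character(lab), c("weak", "strong"))

  expect_equal(as.character(classifyStrength(1.01, boundary = 1.01)), "weak")

  x <- c(0.2, 1.5, 0.9, 3.1, 1.0)
  perm <- c(4, 2, 5, 1, 3)
  expect_identical(classifyStrength(x, 1.01)[perm], classifyStrength(x[perm], 1.01))

  expect_error(classifyStrength(c(0, 1), 1.01), "filtering|excluded")

  # monotone: raising a strength never flips strong -> weak
  xs <- sort(runif(50, 0.1, 3))
  labs <- classifyStrength(xs, 1.01)
  expect_true(all(diff(as.integer(labs)) >= 0))
})

test_that("association tests recover the planted prosody-syntax dependence", {
  cfg <- synthConfig(nWords = 5000, seed = 31)
  tab <- genWordTable(cfg)
  labels <- factor(tab$latent_class, levels = c("weak", "strong"))
  res <- testAssociation(tab, labels)

  expect_gt(res$binomialZ, 0)
  expect_lt(res$binomialP, 0.001)
  expect_lt(res$gammaGlmP, 0.001)
  expect_equal(res$strengthDirection, 1)

  # sign agreement with a Fisher-exact oracle on the 2x2 table
  fe <- fisher.test(res$contingency)
  expect_gt(fe$estimate, 1) # odds of closing higher under strong prosody
  expect_lt(fe$p.value, 0.001)

  # null case: closing independent of prosody
  cfgNull <- synthConfig(
    nWords = 5000, seed = 32,
    pClosingGivenStrong = 0.5, pClosingGivenWeak = 0.5
  )
  tabNull <- genWordTable(cfgNull)
  resNull <- testAssociation(tabNull, factor(tabNull$latent_class, levels = c("weak", "strong")))
  expect_lt(abs(resNull$binomialZ), 3)

  expect_error(
    testAssociation(tab, factor(rep("weak", nrow(tab)), levels = c("weak", "strong"))),
    "two levels"
  )
})

test_that("mixture fits serialize to and from JSON faithfully", {
  set.seed(5)
  x <- c(rgamma(600, 1.1, 2.8), rgamma(600, 14, 10.7))
  fit <- fitGammaMixture(x, seed = 3)
  path <- tempfile(fileext = ".json")
  writeMixtureFit(fit, path)
  back <- readMixtureFit(path)
  expect_equal(back@w, fit@w)
  expect_equal(back@shape, fit@shape)
  expect_equal(back@rate, fit@rate)
  expect_equal(back@boundary, fit@boundary)
  expect_equal(back@converged, fit@converged)
})
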