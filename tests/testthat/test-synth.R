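# Synthetic word tables and recordings.

test_that("generated tables reproduce the configured conditional association", {
  cfg <- synthConfig(nWords = 20000, seed = 42)
  tab <- genWordTable(cfg)
  expect_equal(nrow(tab), 20000)
  expect_true(all(tab$strength > 0))
  expect_true(all(tab$offset_s > tab$onset_s))

  pStrong <- mean(tab$closing[tab$latent_class == "strong"])
  pWeak <- mean(tab$closing[tab$latent_class == "weak"])
  expect_lt(abs(pStrong - 0.72), 0.02)
  expect_lt(abs(pWeak - 0.44), 0.02)
})

test_that("generated strengths follow the configured two-gamma mixture", {
  cfg <- synthConfig(nWords = 50000, seed = 17)
  tab <- genWordTable(cfg)
  # independently drawn reference sample from the same mixture
  set.seed(1234)
  comp <- runif(50000) < cfg@wStrong
  ref <- ifelse(comp,
    rgamma(50000, cfg@gamma2Shape, rate = cfg@gamma2Rate),
    rgamma(50000, cfg@gamma1Shape, rate = cfg@gamma1Rate)
  )
  probs <- seq(0.01, 0.99, by = 0.01)
  qEmp <- quantile(tab$strength, probs)
  qRef <- quantile(ref, probs)
  expect_lt(max(abs(qEmp - qRef)), 0.05)
  expect_gt(suppressWarnings(ks.test(tab$strength, ref)$p.value), 1e-4)
})

test_that("empty tables, determinism and config validation behave", {
  cfg <- synthConfig(nWords = 0)
  expect_equal(nrow(genWordTable(cfg)), 0L)

  cfg2 <- synthConfig(nWords = 200, seed = 7)
  t1 <- genWordTable(cfg2)
  t2 <- genWordTable(cfg2)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))

  expect_error(synthConfig(pClosingGivenStrong = 1.2), "probability")
  expect_error(synthConfig(noiseSd = 0), "positive")
  expect_error(synthConfig(nSubjects = 0), ">= 1")
})

test_that("a configurable fraction of inter-offset gaps violates the 100 ms rule", {
  cfg <- synthConfig(nWords = 2000, shortGapFraction = 0.05, seed = 2)
  tab <- genWordTable(cfg)
  gaps <- diff(tab$offset_s)
  frac <- mean(gaps < 0.1)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("with vanishing noise a single token's epoch matches the planted template", {
  cfg <- synthConfig(
    nWords = 1, nChannels = 8, noiseSd = 1e-12, seed = 5,
    shortGapFraction = 0
  )
  tab <- genWordTable(cfg)
  rec <- genRecording(tab, cfg, subjectSeed = 99)
  es <- extractEpochs(rec,
    offsets = tab$offset_s, tmin = -0.3, tmax = 0.4,
    ids = tab$token_id, labels = tab$closing
  )
  expect_equal(nEpochs(es), 1L)

  # reconstruct the template: signed cell gain x (post + pre raised cosines),
  # evaluated at the true sample times (the offset does not fall on the
  # sample grid, so the epoch time axis is shifted by the rounding residue)
  delta <- round(tab$offset_s * 100) / 100 - tab$offset_s
  t <- epochTimes(es) + delta
  rc <- function(t, peak, width) {
    u <- (t - peak) / width
    ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
  }
  prof <- rc(t, 0.1, 0.3) + cfg@preGain * rc(t, -0.1, 0.2)
  observed <- epochData(es)[1, , ]
  # the channel with the largest energy carries the pattern; its time course
  # must be proportional to the template
  ch <- which.max(rowSums(observed^2))
  expect_gt(abs(cor(observed[ch, ], prof)), 0.999999)
})

test_that("zero-gain recordings are pure noise at chance-level decodability", {
  sc <- smallLabeledCohort(
    nSubjects = 1, nWords = 500, seed = 21,
    gainCoherent = 0, gainNeutral = 0, gainIncoherent = 0, preGain = 0
  )
  sub <- sc$cohort[[1]]
  # the recording is pure Gaussian noise
  dat <- recordingData(sub$recording)
  expect_lt(abs(mean(dat)), 0.01)
  expect_lt(abs(sd(dat) - 1), 0.01)
  expect_gt(suppressWarnings(ks.test(dat[1, ], "pnorm")$p.value), 1e-4)

  # decoding sits at chance up to AUC sampling noise at this test-set size
  prep <- prepareSubject(sub$table, sub$recording, splitSeed = 3, balanceSeed = 4)
  m <- mvpaDecode(prep$train, prep$tests, window = c(0, 0.4), seed = 5)
  expect_true(all(m$meanAuc > 0.35 & m$meanAuc < 0.65))
  expect_lt(abs(mean(m$meanAuc) - 0.5), 0.1)
})

test_that("cohorts are reproducible and sized as configured", {
  cfg <- synthConfig(nSubjects = 3, nWords = 50, nChannels = 4, seed = 13)
  c1 <- genCohort(cfg)
  c2 <- genCohort(cfg)
  expect_length(c1, 3L)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))

  cfg1 <- synthConfig(nSubjects = 1, nWords = 30, nChannels = 4, seed = 13)
  expect_length(genCohort(cfg1), 1L)

  # default cohort size matches the study's sample
  expect_equal(synthConfig()@nSubjects, 11L)
})
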