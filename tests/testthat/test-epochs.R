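# Epoch extraction, the 100 ms discard rule, and SVD reduction.

mkRecording <- function(nChan = 4, dur = 5, fs = 100, offsets = numeric(0), seed = 1) {
  set.seed(seed)
  new("Recording",
    data = matrix(rnorm(nChan * dur * fs), nChan), fs = fs,
    wordOffsets = offsets, wordTableRef = "test"
  )
}

test_that("the discard rule drops the later of two offsets closer than 100 ms", {
  rec <- mkRecording(offsets = c(1.00, 1.05, 2.00))
  es <- extractEpochs(rec, tmin = -0.1, tmax = 0.2)
  expect_equal(nEpochs(es), 2L)
  expect_equal(tokenIds(es), c(1L, 3L))

  # brute-force gap filter over random offset sets
  set.seed(9)
  for (i in 1:20) {
    off <- sort(runif(30, 0.5, 4.5))
    off <- off[c(TRUE, diff(off) > 1e-3)]
    rec2 <- mkRecording(offsets = off)
    es2 <- extractEpochs(rec2, offsets = off, tmin = -0.05, tmax = 0.05)
    keepOracle <- c(TRUE, diff(off) >= 0.1)
    expect_equal(nEpochs(es2), sum(keepOracle))
  }
})

test_that("epoch arithmetic follows the half-open window convention", {
  rec <- mkRecording(dur = 10, offsets = c(2, 5))
  es <- extractEpochs(rec, tmin = -0.4, tmax = 0.8)
  expect_equal(dim(epochData(es))[3], 120L)
  expect_equal(epochTimes(es)[1], -0.4)
  expect_equal(max(epochTimes(es)), 0.8 - 1 / 100)

  # empty offset list is not an error
  es0 <- extractEpochs(rec, offsets = numeric(0), ids = integer(0), labels = logical(0))
  expect_equal(nEpochs(es0), 0L)

  expect_error(extractEpochs(rec, tmin = 0.5, tmax = 0.5), "tmin")

  # epochs that would extend beyond the recording are dropped with a message
  expect_message(
    es2 <- extractEpochs(rec, offsets = c(0.1, 5), tmin = -0.4, tmax = 0.8),
    "discarded"
  )
  expect_equal(nEpochs(es2), 1L)
})

test_that("epoch samples reproduce the underlying recording segment", {
  rec <- mkRecording(nChan = 3, dur = 4, offsets = 2)
  es <- extractEpochs(rec, tmin = -0.1, tmax = 0.1)
  seg <- recordingData(rec)[, (round(2 * 100) + 1 - 10):(round(2 * 100) + 10)]
  expect_equal(epochData(es)[1, , ], seg)
})

test_that("SVD reduction retains energy and respects rank", {
  # rank-1 data: a single spatial pattern
  pat <- c(1, 2, -1, 0.5)
  arr <- array(0, dim = c(6, 4, 10))
  set.seed(4)
  for (e in 1:6) arr[e, , ] <- pat %o% rnorm(10)
  es <- new("EpochSet",
    data = arr, times = (0:9) / 100, tokenIds = 1:6,
    labels = rep(c(TRUE, FALSE), 3), fs = 100
  )
  red <- fitSvdReduction(es)
  expect_equal(nComponents(red), 1L)
  expect_equal(abs(cor(reductionBasis(red)[, 1], pat)), 1, tolerance = 1e-10)

  # noisy data: retained components capture >= 99% of squared Frobenius norm
  set.seed(5)
  arr2 <- array(rnorm(20 * 8 * 12), dim = c(20, 8, 12))
  es2 <- new("EpochSet",
    data = arr2, times = (0:11) / 100, tokenIds = 1:20,
    labels = rep(c(TRUE, FALSE), 10), fs = 100
  )
  red2 <- fitSvdReduction(es2, cutoff = 0.99)
  proj <- applyReduction(es2, red2)
  # reconstruct through the basis and compare energy
  B <- reductionBasis(red2)
  num <- sum(vapply(1:20, function(e) sum((B %*% proj@data[e, , ])^2), numeric(1)))
  den <- sum(arr2^2)
  expect_gte(num / den, 0.99)

  # cutoff = 1 keeps all nonzero components: projection is lossless
  redFull <- fitSvdReduction(es2, cutoff = 1)
  expect_equal(nComponents(redFull), 8L)
  projFull <- applyReduction(es2, redFull)
  rec1 <- reductionBasis(redFull) %*% projFull@data[1, , ]
  expect_equal(rec1, arr2[1, , ], tolerance = 1e-8)

  expect_error(fitSvdReduction(es2, cutoff = 0), "cutoff")
  expect_error(fitSvdReduction(es2, cutoff = 1.5), "cutoff")
})

test_that("the reduction basis is independent of any test data", {
  sc <- smallLabeledCohort(nSubjects = 1, nWords = 300, seed = 19, nChannels = 10)
  sub <- sc$cohort[[1]]
  tab <- sub$table
  es <- extractEpochs(sub$recording,
    offsets = tab$offset_s, ids = tab$token_id,
    labels = tab$closing
  )
  sp <- buildSplit(tab, seed = 2)
  trainEs <- epochsForIds(es, intersect(trainIds(sp), tokenIds(es)))
  redA <- fitSvdReduction(trainEs)
  # refit after perturbing every non-training epoch: identical basis
  idx <- which(!tokenIds(es) %in% trainIds(sp))
  es@data[idx, , ] <- es@data[idx, , ] * 100
  trainEs2 <- epochsForIds(es, intersect(trainIds(sp), tokenIds(es)))
  redB <- fitSvdReduction(trainEs2)
  expect_identical(reductionBasis(redA), reductionBasis(redB))
})

test_that("windowing and id-subsetting preserve structure and multiplicity", {
  sc <- smallLabeledCohort(nSubjects = 1, nWords = 100, seed = 23, nChannels = 5)
  sub <- sc$cohort[[1]]
  es <- extractEpochs(sub$recording,
    offsets = sub$table$offset_s,
    ids = sub$table$token_id, labels = sub$table$closing
  )
  w <- windowEpochs(es, 0, 0.4)
  expect_true(all(epochTimes(w) >= 0 & epochTimes(w) < 0.4))
  expect_equal(dim(epochData(w))[3], 40L)

  ids <- tokenIds(es)[c(1, 1, 5)]
  sub2 <- epochsForIds(es, ids)
  expect_equal(nEpochs(sub2), 3L)
  expect_equal(tokenIds(sub2), ids)
  expect_error(epochsForIds(es, max(tokenIds(es)) + 1L), "no epoch")
})
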