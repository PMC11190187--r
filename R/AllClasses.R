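# Central S4 containers with validity, show and accessors.

# ---------------------------------------------------------------------------
# SynthConfig

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-data generator. The defaults reflect the
#' study conditions the package is designed around: two latent gamma
#' components for prosodic boundary strength with shapes/rates (1.1, 2.8)
#' and (14, 10.7), conditional closing-boundary probabilities of 0.72 given
#' strong prosody and 0.44 given weak prosody, and an 11-subject cohort.
#' See [synthConfig()] for field documentation.
#'
#' @slot nSubjects number of subjects in a cohort.
#' @slot nWords number of word tokens per subject.
#' @slot gamma1Shape,gamma1Rate shape/rate of the weak (smaller-mean) strength component.
#' @slot gamma2Shape,gamma2Rate shape/rate of the strong (larger-mean) component.
#' @slot wStrong marginal probability that a token is drawn from the strong component.
#' @slot pClosingGivenStrong,pClosingGivenWeak conditional probability of a
#'   closing phrase boundary given the latent prosody class.
#' @slot nChannels number of recording channels.
#' @slot fs sampling rate in Hz.
#' @slot gainCoherent,gainNeutral,gainIncoherent response amplitudes for the
#'   coherent cells (strong+closing), the weak+non-closing cell, and the
#'   mismatched cells, in channel units.
#' @slot preGain amplitude of the anticipatory pre-offset response, as a
#'   fraction of the cell gain.
#' @slot noiseSd standard deviation of the additive sensor noise.
#' @slot shortGapFraction fraction of inter-offset gaps forced below 100 ms
#'   so the epoch discard rule is exercised.
#' @slot seed master integer seed.
#' @export
setClass("SynthConfig",
  representation(
    nSubjects = "integer", nWords = "integer",
    gamma1Shape = "numeric", gamma1Rate = "numeric",
    gamma2Shape = "numeric", gamma2Rate = "numeric",
    wStrong = "numeric",
    pClosingGivenStrong = "numeric", pClosingGivenWeak = "numeric",
    nChannels = "integer", fs = "numeric",
    gainCoherent = "numeric", gainNeutral = "numeric",
    gainIncoherent = "numeric", preGain = "numeric",
    noiseSd = "numeric", shortGapFraction = "numeric", seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  for (nm in c("wStrong", "pClosingGivenStrong", "pClosingGivenWeak", "shortGapFraction")) {
    if (!isProb(slot(object, nm))) msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", nm))
  }
  for (nm in c("gamma1Shape", "gamma1Rate", "gamma2Shape", "gamma2Rate", "noiseSd", "fs")) {
    if (!isPositiveScalar(slot(object, nm))) msg <- c(msg, sprintf("'%s' must be a positive scalar", nm))
  }
  for (nm in c("gainCoherent", "gainNeutral", "gainIncoherent", "preGain")) {
    v <- slot(object, nm)
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0)) {
      msg <- c(msg, sprintf("'%s' must be a nonnegative scalar", nm))
    }
  }
  if (!(length(object@nSubjects) == 1L && object@nSubjects >= 1L)) {
    msg <- c(msg, "'nSubjects' must be >= 1")
  }
  if (!(length(object@nWords) == 1L && object@nWords >= 0L)) {
    msg <- c(msg, "'nWords' must be >= 0")
  }
  if (!(length(object@nChannels) == 1L && object@nChannels >= 1L)) {
    msg <- c(msg, "'nChannels' must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nSubjects, "subject(s),", object@nWords, "words/subject\n")
  cat(sprintf(
    "  strength mixture: %.2f x Gamma(%.3g, %.3g) + %.2f x Gamma(%.3g, %.3g)\n",
    1 - object@wStrong, object@gamma1Shape, object@gamma1Rate,
    object@wStrong, object@gamma2Shape, object@gamma2Rate
  ))
  cat(sprintf(
    "  P(closing | strong) = %.2f, P(closing | weak) = %.2f\n",
    object@pClosingGivenStrong, object@pClosingGivenWeak
  ))
  cat(sprintf(
    "  %d channels @ %g Hz; gains c/n/i = %.3g/%.3g/%.3g, pre %.3g, noise sd %.3g; seed %d\n",
    object@nChannels, object@fs, object@gainCoherent, object@gainNeutral,
    object@gainIncoherent, object@preGain, object@noiseSd, object@seed
  ))
})

# ---------------------------------------------------------------------------
# Recording

#' Continuous multichannel recording
#'
#' A channels-by-samples matrix with its sampling rate and the word-offset
#' event times (seconds) used for epoching. Offsets must be strictly
#' increasing and lie within the recording duration.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot wordOffsets word offset times in seconds, strictly increasing.
#' @slot wordTableRef identifier linking the offsets to word-table rows.
#' @export
setClass("Recording",
  representation(
    data = "matrix", fs = "numeric",
    wordOffsets = "numeric", wordTableRef = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "'data' must be a numeric matrix")
  if (!isPositiveScalar(object@fs)) msg <- c(msg, "'fs' must be a positive scalar")
  off <- object@wordOffsets
  if (length(off)) {
    if (any(diff(off) <= 0)) msg <- c(msg, "'wordOffsets' must be strictly increasing")
    dur <- ncol(object@data) / object@fs
    if (any(off < 0) || any(off > dur)) {
      msg <- c(msg, sprintf("word offsets must lie within the recording duration (%.3f s)", dur))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Recording-class
#' @export
setMethod("samplingRate", "Recording", function(object) object@fs)

#' @rdname Recording-class
#' @export
setMethod("wordOffsets", "Recording", function(object) object@wordOffsets)

#' @rdname Recording-class
#' @export
setMethod("recordingData", "Recording", function(object) object@data)

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording: %d channels x %d samples @ %g Hz (%.1f s), %d word offsets\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs, length(object@wordOffsets)
  ))
})

# ---------------------------------------------------------------------------
# GammaMixtureFit

#' Two-component gamma mixture fit
#'
#' Result of [fitGammaMixture()]. Components are ordered so that component 2
#' has the larger mean (shape/rate); `boundary` is the strength value between
#' the component means at which the weighted densities (and hence posterior
#' membership probabilities) are equal, or `NA` for a degenerate fit.
#'
#' @slot w mixture weights (length 2, summing to 1).
#' @slot shape,rate component shapes and rates (length 2, positive).
#' @slot loglik log-likelihood of the returned fit.
#' @slot boundary weak/strong binarization boundary (equal-posterior crossing).
#' @slot nIter EM iterations used by the best restart.
#' @slot converged whether EM met the relative log-likelihood tolerance.
#' @slot loglikTrace per-iteration log-likelihood of the best restart.
#' @export
setClass("GammaMixtureFit",
  representation(
    w = "numeric", shape = "numeric", rate = "numeric",
    loglik = "numeric", boundary = "numeric",
    nIter = "integer", converged = "logical", loglikTrace = "numeric"
  )
)

setValidity("GammaMixtureFit", function(object) {
  msg <- character()
  if (length(object@w) != 2L || abs(sum(object@w) - 1) > 1e-12 || any(object@w < 0)) {
    msg <- c(msg, "'w' must be two nonnegative weights summing to 1 (tol 1e-12)")
  }
  if (length(object@shape) != 2L || any(object@shape <= 0)) msg <- c(msg, "'shape' must be two positive reals")
  if (length(object@rate) != 2L || any(object@rate <= 0)) msg <- c(msg, "'rate' must be two positive reals")
  if (length(object@shape) == 2L && length(object@rate) == 2L &&
    all(object@shape > 0) && all(object@rate > 0)) {
    mu <- object@shape / object@rate
    if (mu[2] < mu[1]) msg <- c(msg, "component 2 must have the larger mean")
  }
  tr <- object@loglikTrace
  if (length(tr) > 1L && any(diff(tr) < -1e-6 * (1 + abs(tr[-length(tr)])))) {
    msg <- c(msg, "EM log-likelihood trace must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GammaMixtureFit-class
#' @export
setMethod("mixtureParameters", "GammaMixtureFit", function(fit) {
  data.frame(
    component = c(1L, 2L), w = fit@w, shape = fit@shape, rate = fit@rate,
    mean = fit@shape / fit@rate
  )
})

setMethod("show", "GammaMixtureFit", function(object) {
  cat("Two-component gamma mixture fit\n")
  cat(sprintf(
    "  comp 1 (weak):   w = %.3f, shape = %.3f, rate = %.3f (mean %.3f)\n",
    object@w[1], object@shape[1], object@rate[1], object@shape[1] / object@rate[1]
  ))
  cat(sprintf(
    "  comp 2 (strong): w = %.3f, shape = %.3f, rate = %.3f (mean %.3f)\n",
    object@w[2], object@shape[2], object@rate[2], object@shape[2] / object@rate[2]
  ))
  cat(sprintf(
    "  boundary = %s, loglik = %.3f, %d iteration(s), converged: %s\n",
    ifelse(is.na(object@boundary), "NA", sprintf("%.4f", object@boundary)),
    object@loglik, object@nIter, object@converged
  ))
})

# ---------------------------------------------------------------------------
# EpochSet

#' Word-offset-locked epochs
#'
#' A trial tensor (epochs x components x samples) with a time axis in
#' seconds relative to word offset, per-epoch token ids and binary
#' closing-boundary labels. Before SVD reduction the component axis holds
#' raw channels.
#'
#' @slot data numeric array, epochs x components x samples.
#' @slot times sample times in seconds relative to word offset (uniform step 1/fs).
#' @slot tokenIds integer token ids, one per epoch.
#' @slot labels logical closing-boundary labels, one per epoch.
#' @slot fs sampling rate in Hz.
#' @export
setClass("EpochSet",
  representation(
    data = "array", times = "numeric", tokenIds = "integer",
    labels = "logical", fs = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) {
    msg <- c(msg, "'data' must be a 3-d array (epochs x components x samples)")
    return(msg)
  }
  if (length(object@times) != d[3]) msg <- c(msg, "'times' length must equal the sample dimension")
  if (length(object@times) > 1L) {
    st <- diff(object@times)
    if (any(st <= 0)) msg <- c(msg, "'times' must be strictly increasing")
    if (max(abs(st - 1 / object@fs)) > 1e-9) msg <- c(msg, "'times' must have uniform step 1/fs")
  }
  if (length(object@tokenIds) != d[1]) msg <- c(msg, "'tokenIds' length must equal the epoch count")
  if (length(object@labels) != d[1]) msg <- c(msg, "'labels' length must equal the epoch count")
  if (!isPositiveScalar(object@fs)) msg <- c(msg, "'fs' must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)

#' @rdname EpochSet-class
#' @export
setMethod("epochTimes", "EpochSet", function(object) object@times)

#' @rdname EpochSet-class
#' @export
setMethod("epochLabels", "EpochSet", function(object) object@labels)

#' @rdname EpochSet-class
#' @export
setMethod("tokenIds", "EpochSet", function(object) object@tokenIds)

#' @rdname EpochSet-class
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@data)[1])

#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  rng <- if (d[3]) sprintf("[%.3f, %.3f] s", object@times[1], object@times[d[3]]) else "[]"
  cat(sprintf(
    "EpochSet: %d epoch(s) x %d component(s) x %d sample(s) %s @ %g Hz; %d closing / %d non-closing\n",
    d[1], d[2], d[3], rng, object@fs, sum(object@labels), sum(!object@labels)
  ))
})

# ---------------------------------------------------------------------------
# SvdReduction

#' SVD dimensionality reduction
#'
#' Orthonormal spatial basis fitted on training epochs, retaining the
#' smallest leading set of components whose cumulative energy reaches the
#' cutoff (99% by default).
#'
#' @slot basis channels x components orthonormal projection matrix.
#' @slot d all singular values of the training matrix.
#' @slot varianceFraction fraction of squared-singular-value energy retained.
#' @slot cutoff the requested cutoff.
#' @slot energy `"squared"` (variance) or `"linear"` (raw singular values).
#' @export
setClass("SvdReduction",
  representation(
    basis = "matrix", d = "numeric", varianceFraction = "numeric",
    cutoff = "numeric", energy = "character"
  )
)

setValidity("SvdReduction", function(object) {
  msg <- character()
  B <- object@basis
  if (ncol(B) < 1L) msg <- c(msg, "at least one component must be retained")
  G <- crossprod(B)
  if (max(abs(G - diag(ncol(B)))) > 1e-8) msg <- c(msg, "'basis' columns must be orthonormal")
  if (!(object@varianceFraction >= 0 && object@varianceFraction <= 1 + 1e-12)) {
    msg <- c(msg, "'varianceFraction' must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SvdReduction-class
#' @export
setMethod("reductionBasis", "SvdReduction", function(object) object@basis)

#' @rdname SvdReduction-class
#' @export
setMethod("nComponents", "SvdReduction", function(object) ncol(object@basis))

setMethod("show", "SvdReduction", function(object) {
  cat(sprintf(
    "SvdReduction: %d/%d component(s) retained (%s energy %.4f >= cutoff %.2f)\n",
    ncol(object@basis), nrow(object@basis), object@energy,
    object@varianceFraction, object@cutoff
  ))
})

# ---------------------------------------------------------------------------
# SplitDesign

#' Train/test split into neutral, coherent and incoherent sets
#'
#' Token-id design produced by [buildSplit()]: a class-balanced training
#' pool of weak-prosody tokens and three balanced test sets. Test sets may
#' contain duplicated ids (resampling within an undersized cell); no id is
#' shared between the training pool and any test set.
#'
#' @slot trainIds training-pool token ids (weak prosody, class-balanced).
#' @slot testNeutral,testCoherent,testIncoherent test-set token id multisets.
#' @slot classCounts 3 x 2 matrix of per-set class counts (rows: neutral,
#'   coherent, incoherent; columns: closing, non-closing).
#' @slot testSizePerClass tokens per class per test set.
#' @slot seed RNG seed used to draw the split.
#' @export
setClass("SplitDesign",
  representation(
    trainIds = "integer", testNeutral = "integer",
    testCoherent = "integer", testIncoherent = "integer",
    classCounts = "matrix", testSizePerClass = "integer", seed = "integer"
  )
)

setValidity("SplitDesign", function(object) {
  msg <- character()
  tests <- list(object@testNeutral, object@testCoherent, object@testIncoherent)
  sizes <- lengths(tests)
  if (length(unique(sizes)) != 1L) msg <- c(msg, "the three test sets must have equal total size")
  cc <- object@classCounts
  if (!all(dim(cc) == c(3L, 2L))) {
    msg <- c(msg, "'classCounts' must be 3 x 2")
  } else if (any(cc[, 1] != cc[, 2])) {
    msg <- c(msg, "each test set must have equal closing and non-closing counts")
  }
  overlap <- intersect(object@trainIds, unique(unlist(tests)))
  if (length(overlap)) msg <- c(msg, "training ids must not appear in any test set")
  if (anyDuplicated(object@trainIds)) msg <- c(msg, "training ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname SplitDesign-class
#' @export
setMethod("trainIds", "SplitDesign", function(object) object@trainIds)

#' @rdname SplitDesign-class
#' @export
setMethod("testIds", "SplitDesign", function(object, set) {
  set <- match.arg(set, c("neutral", "coherent", "incoherent"))
  switch(set,
    neutral = object@testNeutral,
    coherent = object@testCoherent,
    incoherent = object@testIncoherent
  )
})

setMethod("show", "SplitDesign", function(object) {
  cat(sprintf(
    "SplitDesign: train %d, test sets %d each (%d per class); seed %d\n",
    length(object@trainIds), length(object@testNeutral),
    object@testSizePerClass, object@seed
  ))
})
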