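# Word-offset-locked epoching and SVD dimensionality reduction.

#' Extract word-offset-locked epochs
#'
#' Cuts one epoch per retained offset over the half-open window
#' `[tmin, tmax)`, with time 0 at the word offset and
#' `round((tmax - tmin) * fs)` samples per epoch. An offset is discarded
#' when its gap to the preceding offset is below 100 ms (the later of the
#' two is dropped); epochs extending past either end of the recording are
#' discarded with a message reporting the count.
#'
#' @param rec a [Recording-class].
#' @param offsets event times in seconds (default: the recording's word
#'   offsets); must be sorted ascending.
#' @param tmin,tmax epoch window in seconds relative to word offset
#'   (`tmin < tmax`).
#' @param ids integer token ids aligned with `offsets` (default
#'   `seq_along(offsets)`).
#' @param labels logical closing-boundary labels aligned with `offsets`
#'   (default `NA`).
#' @param minGap minimum inter-offset interval in seconds (default 0.1).
#' @return an [EpochSet-class] (empty when no offsets survive; an empty
#'   offset vector is not an error).
#' @export
extractEpochs <- function(rec, offsets = wordOffsets(rec), tmin = -0.4, tmax = 0.8,
                          ids = seq_along(offsets), labels = rep(NA, length(offsets)),
                          minGap = 0.1) {
  stopifnot(is(rec, "Recording"))
  if (tmin >= tmax) stopf("'tmin' must be smaller than 'tmax'")
  if (length(offsets) && any(diff(offsets) < 0)) stopf("'offsets' must be sorted ascending")
  if (length(ids) != length(offsets) || length(labels) != length(offsets)) {
    stopf("'ids' and 'labels' must be aligned with 'offsets'")
  }
  fs <- samplingRate(rec)
  nSamp <- round((tmax - tmin) * fs)
  times <- tmin + (seq_len(nSamp) - 1) / fs
  dat <- recordingData(rec)
  nChan <- nrow(dat)
  total <- ncol(dat)

  keepGap <- if (length(offsets)) c(TRUE, diff(offsets) >= minGap) else logical(0)
  startIdx <- round(offsets * fs) + 1L + round(tmin * fs)
  inRange <- startIdx >= 1L & (startIdx + nSamp - 1L) <= total
  nOut <- sum(keepGap & !inRange)
  if (nOut > 0L) {
    message(nOut, " epoch(s) discarded: window extends past the recording")
  }
  keep <- which(keepGap & inRange)

  arr <- array(0, dim = c(length(keep), nChan, nSamp))
  for (j in seq_along(keep)) {
    i <- keep[j]
    arr[j, , ] <- dat[, startIdx[i]:(startIdx[i] + nSamp - 1L)]
  }
  new("EpochSet",
    data = arr, times = times, tokenIds = as.integer(ids[keep]),
    labels = as.logical(labels[keep]), fs = fs
  )
}

# Unfold an EpochSet into a components x (samples * epochs) matrix.
unfoldEpochs <- function(es) {
  d <- dim(es@data)
  matrix(aperm(es@data, c(2, 3, 1)), nrow = d[2])
}

#' Fit an SVD reduction on training epochs
#'
#' Singular value decomposition of the channels-by-(epochs x samples)
#' training matrix. The smallest leading set of components whose cumulative
#' energy reaches `cutoff` is retained; by default energy is the squared
#' singular values (variance), with `energy = "linear"` switching to the
#' raw singular value spectrum. The projection must be fitted on training
#' epochs only and applied unchanged to test epochs.
#'
#' @param trainEpochs a nonempty [EpochSet-class].
#' @param cutoff cumulative energy cutoff in (0, 1] (default 0.99).
#' @param energy `"squared"` (default) or `"linear"`.
#' @return an [SvdReduction-class].
#' @export
fitSvdReduction <- function(trainEpochs, cutoff = 0.99, energy = c("squared", "linear")) {
  stopifnot(is(trainEpochs, "EpochSet"))
  energy <- match.arg(energy)
  if (nEpochs(trainEpochs) < 1L) stopf("training epochs must be nonempty")
  if (!(cutoff > 0 && cutoff <= 1)) stopf("'cutoff' must lie in (0, 1]")
  X <- unfoldEpochs(trainEpochs)
  eig <- eigen(tcrossprod(X), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  d <- sqrt(vals)
  nz <- sum(d > max(d) * 1e-12)
  w <- if (energy == "squared") vals else d
  cum <- cumsum(w) / sum(w)
  k <- which(cum >= cutoff - 1e-12)[1]
  k <- min(max(k, 1L), nz)
  new("SvdReduction",
    basis = eig$vectors[, seq_len(k), drop = FALSE], d = d,
    varianceFraction = cumsum(vals)[k] / sum(vals),
    cutoff = cutoff, energy = energy
  )
}

#' Project epochs onto a fitted SVD basis
#'
#' @param epochs an [EpochSet-class] (channel-space).
#' @param reduction an [SvdReduction-class] fitted on training epochs.
#' @return an [EpochSet-class] in component space.
#' @export
applyReduction <- function(epochs, reduction) {
  stopifnot(is(epochs, "EpochSet"), is(reduction, "SvdReduction"))
  d <- dim(epochs@data)
  if (d[2] != nrow(reduction@basis)) {
    stopf(
      "epoch channel count (%d) does not match the reduction basis (%d)",
      d[2], nrow(reduction@basis)
    )
  }
  k <- ncol(reduction@basis)
  if (d[1] == 0L) {
    return(new("EpochSet",
      data = array(0, dim = c(0L, k, d[3])), times = epochs@times,
      tokenIds = epochs@tokenIds, labels = epochs@labels, fs = epochs@fs
    ))
  }
  proj <- crossprod(reduction@basis, unfoldEpochs(epochs)) # k x (samples*epochs)
  arr <- aperm(array(proj, dim = c(k, d[3], d[1])), c(3, 1, 2))
  new("EpochSet",
    data = arr, times = epochs@times, tokenIds = epochs@tokenIds,
    labels = epochs@labels, fs = epochs@fs
  )
}

#' Subset an EpochSet
#'
#' `epochsForIds()` selects epochs by token id, preserving multiset
#' multiplicity (an id requested twice yields its epoch twice), as needed
#' for resampled test sets. `windowEpochs()` restricts the time axis to the
#' half-open window `[t0, t1)`.
#'
#' @param es an [EpochSet-class].
#' @param ids token ids (multiset).
#' @return an [EpochSet-class].
#' @export
epochsForIds <- function(es, ids) {
  stopifnot(is(es, "EpochSet"))
  pos <- match(as.integer(ids), es@tokenIds)
  if (anyNA(pos)) {
    stopf("%d requested token id(s) have no epoch (discarded or never epoched)", sum(is.na(pos)))
  }
  new("EpochSet",
    data = es@data[pos, , , drop = FALSE], times = es@times,
    tokenIds = es@tokenIds[pos], labels = es@labels[pos], fs = es@fs
  )
}

#' Randomly permute the class labels of an epoch set
#'
#' Breaks the label-feature mapping while leaving the data untouched; used
#' for chance-level (empirical null) checks of the decoders.
#'
#' @param es an [EpochSet-class].
#' @param seed RNG seed for the permutation.
#' @return an [EpochSet-class] with shuffled labels.
#' @export
permuteEpochLabels <- function(es, seed = 1) {
  stopifnot(is(es, "EpochSet"))
  es@labels <- withSeed(seed, sample(es@labels))
  es
}

#' @rdname epochsForIds
#' @param t0,t1 window bounds in seconds (half-open, `t0 <= t < t1`).
#' @export
windowEpochs <- function(es, t0, t1) {
  stopifnot(is(es, "EpochSet"))
  if (t0 >= t1) stopf("'t0' must be smaller than 't1'")
  sel <- which(es@times >= t0 - 1e-9 & es@times < t1 - 1e-9)
  if (!length(sel)) stopf("window [%g, %g) contains no samples", t0, t1)
  new("EpochSet",
    data = es@data[, , sel, drop = FALSE], times = es@times[sel],
    tokenIds = es@tokenIds, labels = es@labels, fs = es@fs
  )
}
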