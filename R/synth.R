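# Synthetic word tables and recordings with the statistical structure the
# analysis assumes: a two-gamma strength mixture, a conditional
# prosody-syntax association, and epochs whose class-discriminative SNR
# depends on the prosody-syntax coherence of each token.

#' Create a synthetic cohort configuration
#'
#' Defaults encode the study conditions the downstream analysis expects:
#' strength components Gamma(1.1, 2.8) and Gamma(14, 10.7), closing-boundary
#' probabilities 0.72 (strong prosody) and 0.44 (weak prosody), and 11
#' subjects. The marginal rate of strong tokens (`wStrong`) and the
#' signal/noise amplitudes are free simulation parameters; see the methods
#' vignette for the rationale behind their defaults.
#'
#' @param nSubjects subjects per cohort (default 11).
#' @param nWords word tokens per subject (default 800).
#' @param gamma1Shape,gamma1Rate weak strength component (defaults 1.1, 2.8).
#' @param gamma2Shape,gamma2Rate strong strength component (defaults 14, 10.7).
#' @param wStrong marginal probability of the strong component (default 0.25).
#' @param pClosingGivenStrong,pClosingGivenWeak conditional closing-boundary
#'   probabilities (defaults 0.72, 0.44).
#' @param nChannels recording channels (default 60).
#' @param fs sampling rate in Hz (default 100).
#' @param gainCoherent,gainNeutral,gainIncoherent post-offset response
#'   amplitudes for the strong+closing cell, the weak+non-closing cell, and
#'   the two mismatched cells (defaults 0.5, 0.3, 0.15).
#' @param preGain anticipatory pre-offset response amplitude as a fraction of
#'   the cell gain (default 0.4).
#' @param noiseSd sensor noise standard deviation (default 1).
#' @param shortGapFraction fraction of inter-offset gaps forced below 100 ms
#'   (default 0.05) so the epoch discard rule is exercised.
#' @param seed master integer seed.
#' @return a validated [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nSubjects = 2, nWords = 100, seed = 1)
#' tab <- genWordTable(cfg)
#' head(tab)
#' @export
synthConfig <- function(nSubjects = 11, nWords = 800,
                        gamma1Shape = 1.1, gamma1Rate = 2.8,
                        gamma2Shape = 14, gamma2Rate = 10.7,
                        wStrong = 0.25,
                        pClosingGivenStrong = 0.72, pClosingGivenWeak = 0.44,
                        nChannels = 60, fs = 100,
                        gainCoherent = 0.5, gainNeutral = 0.3,
                        gainIncoherent = 0.15, preGain = 0.4,
                        noiseSd = 1, shortGapFraction = 0.05, seed = 1) {
  cfg <- try(new("SynthConfig",
    nSubjects = as.integer(nSubjects), nWords = as.integer(nWords),
    gamma1Shape = gamma1Shape, gamma1Rate = gamma1Rate,
    gamma2Shape = gamma2Shape, gamma2Rate = gamma2Rate,
    wStrong = wStrong,
    pClosingGivenStrong = pClosingGivenStrong,
    pClosingGivenWeak = pClosingGivenWeak,
    nChannels = as.integer(nChannels), fs = fs,
    gainCoherent = gainCoherent, gainNeutral = gainNeutral,
    gainIncoherent = gainIncoherent, preGain = preGain,
    noiseSd = noiseSd, shortGapFraction = shortGapFraction,
    seed = as.integer(seed)
  ), silent = TRUE)
  if (inherits(cfg, "try-error")) {
    stopf("invalid synthetic configuration: %s", attr(cfg, "condition")$message)
  }
  cfg
}

#' Generate a synthetic word table
#'
#' Samples the latent prosody class first (strong with probability
#' `wStrong`), draws the closing-boundary label from the class-conditional
#' probability, and draws the strength from the class's gamma component.
#' This direction of generation plants exactly the conditional association
#' the stimulus analysis measures. Word offsets are spaced by a shifted
#' exponential, with a configurable fraction of gaps forced under 100 ms.
#'
#' @param cfg a [SynthConfig-class].
#' @param seed optional seed overriding `cfg@seed`.
#' @return a `data.frame` with columns `token_id`, `talk_id`, `sentence_id`,
#'   `word`, `onset_s`, `offset_s`, `strength`, `latent_class`
#'   (`"weak"`/`"strong"`) and `closing` (logical).
#' @export
genWordTable <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  n <- cfg@nWords
  cols <- c(
    "token_id", "talk_id", "sentence_id", "word", "onset_s", "offset_s",
    "strength", "latent_class", "closing"
  )
  if (n == 0L) {
    out <- data.frame(
      token_id = integer(), talk_id = integer(), sentence_id = integer(),
      word = character(), onset_s = numeric(), offset_s = numeric(),
      strength = numeric(), latent_class = character(), closing = logical(),
      stringsAsFactors = FALSE
    )
    return(out[, cols])
  }
  if (is.null(seed)) seed <- cfg@seed
  withSeed(seed, {
    strong <- runif(n) < cfg@wStrong
    pClose <- ifelse(strong, cfg@pClosingGivenStrong, cfg@pClosingGivenWeak)
    closing <- runif(n) < pClose
    strength <- numeric(n)
    strength[!strong] <- rgamma(sum(!strong), shape = cfg@gamma1Shape, rate = cfg@gamma1Rate)
    strength[strong] <- rgamma(sum(strong), shape = cfg@gamma2Shape, rate = cfg@gamma2Rate)

    # inter-offset gaps: shifted exponential, with a forced short-gap subset
    gaps <- 0.12 + rexp(n, rate = 1 / 0.18)
    nShort <- floor(cfg@shortGapFraction * n)
    if (nShort > 0L) {
      shortIdx <- sample(seq_len(n), nShort)
      gaps[shortIdx] <- runif(nShort, 0.02, 0.09)
    }
    offsets <- 0.5 + cumsum(gaps)
    onsets <- offsets - pmax(0.05, 0.6 * gaps)

    sentLen <- pmax(3L, stats::rpois(n, lambda = 9L))
    sentenceId <- rep.int(seq_along(sentLen), sentLen)[seq_len(n)]

    data.frame(
      token_id = seq_len(n), talk_id = 1L, sentence_id = sentenceId,
      word = sprintf("w%05d", seq_len(n)),
      onset_s = onsets, offset_s = offsets, strength = strength,
      latent_class = ifelse(strong, "strong", "weak"), closing = closing,
      stringsAsFactors = FALSE
    )
  })
}

# Raised-cosine bump: peak 1 at `peak`, support width `width`, zero outside.
raisedCosine <- function(t, peak, width) {
  u <- (t - peak) / width
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# Per-cell response amplitude: strong+closing -> gainCoherent,
# weak+non-closing -> gainNeutral, mismatched cells -> gainIncoherent.
cellGain <- function(strong, closing, cfg) {
  ifelse(strong & closing, cfg@gainCoherent,
    ifelse(!strong & !closing, cfg@gainNeutral, cfg@gainIncoherent)
  )
}

#' Generate a synthetic recording for one subject
#'
#' The recording is Gaussian sensor noise plus, for every token, a fixed
#' per-subject random spatial pattern times a raised-cosine temporal
#' profile (width 300 ms, peaking 100 ms after the token's offset), signed
#' positive for closing-boundary tokens and negative for non-closing
#' tokens, and scaled by the token's cell gain. A smaller anticipatory
#' component (width 200 ms, peaking 100 ms before offset, amplitude
#' `preGain` times the cell gain) produces above-chance pre-offset
#' decodability.
#'
#' @param table a word table from [genWordTable()] (nonempty).
#' @param cfg a [SynthConfig-class].
#' @param subjectSeed integer seed for this subject's noise and spatial
#'   pattern.
#' @return a [Recording-class].
#' @export
genRecording <- function(table, cfg, subjectSeed) {
  stopifnot(is(cfg, "SynthConfig"))
  if (!NROW(table)) stopf("word table must be nonempty")
  offsets <- table$offset_s
  if (any(diff(offsets) <= 0)) stopf("word offsets must be strictly increasing")
  fs <- cfg@fs
  duration <- max(offsets) + 1
  nSamp <- round(duration * fs)
  if (any(offsets > nSamp / fs)) stopf("word offsets extend past the recording duration")

  withSeed(subjectSeed, {
    pattern <- rnorm(cfg@nChannels)
    pattern <- pattern / sqrt(sum(pattern^2))
    dat <- matrix(
      rnorm(cfg@nChannels * nSamp, sd = cfg@noiseSd),
      nrow = cfg@nChannels, ncol = nSamp
    )
  })

  strong <- table$latent_class == "strong"
  amp <- ifelse(table$closing, 1, -1) * cellGain(strong, table$closing, cfg)

  # token response support: pre component [-0.2, 0], post component [-0.05, 0.25]
  for (i in seq_along(offsets)) {
    if (amp[i] == 0) next
    lo <- max(1L, floor((offsets[i] - 0.25) * fs) + 1L)
    hi <- min(nSamp, ceiling((offsets[i] + 0.30) * fs) + 1L)
    idx <- lo:hi
    t <- (idx - 1) / fs - offsets[i]
    prof <- raisedCosine(t, 0.1, 0.3) + cfg@preGain * raisedCosine(t, -0.1, 0.2)
    dat[, idx] <- dat[, idx] + amp[i] * tcrossprod(pattern, prof)
  }

  new("Recording",
    data = dat, fs = fs, wordOffsets = offsets,
    wordTableRef = sprintf("seed%d", as.integer(subjectSeed))
  )
}

#' Generate a multi-subject synthetic cohort
#'
#' Per-subject word tables and recordings with RNG substreams derived
#' deterministically from `cfg@seed`, so identical configurations yield
#' identical cohorts.
#'
#' @param cfg a [SynthConfig-class].
#' @return a list of `nSubjects` elements, each `list(table =, recording =)`.
#' @export
genCohort <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  out <- lapply(seq_len(cfg@nSubjects), function(i) {
    tab <- genWordTable(cfg, seed = deriveSeed(cfg@seed, 1L, i))
    rec <- genRecording(tab, cfg, subjectSeed = deriveSeed(cfg@seed, 2L, i))
    list(table = tab, recording = rec)
  })
  names(out) <- sprintf("subject%02d", seq_len(cfg@nSubjects))
  out
}
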