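# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic integer stream derivation so that cohort members, restarts
#' and folds each consume an independent, reproducible RNG substream. The
#' result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param stream integer stream id (one per consumer kind).
#' @param index integer index within the stream.
#' @return a single integer seed.
#' @export
deriveSeed <- function(seed, stream = 0L, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(seed) %% m)
  s <- (s * 48271 + stream * 1009 + index * 101 + 12345) %% m
  # avoid 0 which set.seed accepts but keep away from degenerate streams
  as.integer(s %% (m - 2L) + 1L)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# scalar checks -------------------------------------------------------------

isProb <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

isPositiveScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
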