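# Balanced training pool and the neutral/coherent/incoherent test sets.

#' Assign tokens to prosody-by-syntax cells
#'
#' The 2x2 cells underlying the generalization sets: neutral draws from
#' weak.no and weak.yes, coherent from weak.no and strong.yes (the
#' statistically co-occurring combinations), incoherent from weak.yes and
#' strong.no (the mismatched combinations).
#'
#' @param prosodyClass `"weak"`/`"strong"` per token (no `NA`: excluded or
#'   unassigned tokens are an error).
#' @param closing logical closing-boundary label per token.
#' @return a factor with levels `weak.no`, `weak.yes`, `strong.no`,
#'   `strong.yes`.
#' @examples
#' assignCell(c("weak", "strong"), c(TRUE, TRUE))
#' @export
assignCell <- function(prosodyClass, closing) {
  prosodyClass <- as.character(prosodyClass)
  if (length(prosodyClass) != length(closing)) stopf("inputs must be aligned")
  if (any(is.na(prosodyClass)) || any(is.na(closing))) {
    stopf("excluded or unassigned tokens cannot be assigned to a cell")
  }
  if (!all(prosodyClass %in% c("weak", "strong"))) {
    stopf("prosody class must be 'weak' or 'strong'")
  }
  factor(
    paste0(prosodyClass, ".", ifelse(closing, "yes", "no")),
    levels = c("weak.no", "weak.yes", "strong.no", "strong.yes")
  )
}

#' Build the training pool and the three balanced test sets
#'
#' Reserves `testSizePerClass` tokens from each of the four
#' prosody-by-syntax cells -- sampling with replacement within a cell only
#' when the cell holds fewer tokens than required -- and assembles the test
#' sets from their defining cells: neutral = weak.no + weak.yes, coherent =
#' weak.no + strong.yes, incoherent = weak.yes + strong.no. Each weak-cell
#' reservation is shared by the two test sets that draw on it. All
#' remaining (unreserved) weak tokens form the training pool, with the
#' majority class downsampled so the pool is exactly class-balanced; no
#' token id appears in both the training pool and any test set.
#'
#' @param table a word table with columns `token_id`, `prosody_class`
#'   (`"weak"`/`"strong"`) and `closing` (logical); excluded rows (if an
#'   `excluded` column is present) are dropped first.
#' @param testSizePerClass tokens per syntactic class per test set. Default:
#'   the smallest cell size, capped so the training pool keeps at least 70%
#'   of the weak tokens.
#' @param seed RNG seed for the reservation and downsampling draws.
#' @return a [SplitDesign-class].
#' @export
buildSplit <- function(table, testSizePerClass = NULL, seed = 1) {
  table <- analysisTable(table)
  need <- c("token_id", "prosody_class", "closing")
  if (!all(need %in% names(table))) {
    stopf("table must have columns %s", paste(need, collapse = ", "))
  }
  cell <- assignCell(table$prosody_class, table$closing)
  ids <- split(as.integer(table$token_id), cell)
  sizes <- lengths(ids)
  if (any(sizes == 0L)) {
    stopf(
      "empty prosody-by-syntax cell(s): %s",
      paste(names(sizes)[sizes == 0L], collapse = ", ")
    )
  }
  nWeak <- sizes[["weak.no"]] + sizes[["weak.yes"]]
  if (is.null(testSizePerClass)) {
    testSizePerClass <- min(min(sizes), floor(0.15 * nWeak))
    if (testSizePerClass < 1L) stopf("too few tokens to reserve a test set")
  }
  testSizePerClass <- as.integer(testSizePerClass)
  if (testSizePerClass < 1L) stopf("'testSizePerClass' must be >= 1")
  if (2L * testSizePerClass >= nWeak) {
    stopf(
      "'testSizePerClass' (%d) exceeds what the weak pool (%d tokens) can support",
      testSizePerClass, nWeak
    )
  }

  withSeed(seed, {
    reserve <- lapply(ids, function(pool) {
      sample(pool, testSizePerClass, replace = length(pool) < testSizePerClass)
    })
    testNeutral <- c(reserve$weak.no, reserve$weak.yes)
    testCoherent <- c(reserve$weak.no, reserve$strong.yes)
    testIncoherent <- c(reserve$weak.yes, reserve$strong.no)

    reservedWeak <- unique(c(reserve$weak.no, reserve$weak.yes))
    poolNo <- setdiff(ids$weak.no, reservedWeak)
    poolYes <- setdiff(ids$weak.yes, reservedWeak)
    k <- min(length(poolNo), length(poolYes))
    if (k < 1L) stopf("no weak tokens left for the training pool after reservation")
    train <- c(
      if (length(poolNo) > k) sample(poolNo, k) else poolNo,
      if (length(poolYes) > k) sample(poolYes, k) else poolYes
    )
  })

  classCounts <- matrix(
    rep(testSizePerClass, 6L), 3, 2,
    dimnames = list(c("neutral", "coherent", "incoherent"), c("closing", "nonclosing"))
  )
  new("SplitDesign",
    trainIds = as.integer(train),
    testNeutral = as.integer(testNeutral),
    testCoherent = as.integer(testCoherent),
    testIncoherent = as.integer(testIncoherent),
    classCounts = classCounts,
    testSizePerClass = testSizePerClass, seed = as.integer(seed)
  )
}
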