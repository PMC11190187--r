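# Plain-text interchange formats: TSV word tables, JSON fits/splits/results,
# and a JSON-based recording container.

#' Read and write word tables
#'
#' Tab-separated tables with a header; the canonical columns are
#' `token_id`, `talk_id`, `sentence_id`, `word`, `onset_s`, `offset_s`,
#' `strength`, `closing` (plus any extra columns present).
#'
#' @param path file path.
#' @return `readWordTable()` returns a `data.frame`.
#' @export
readWordTable <- function(path) {
  if (!file.exists(path)) stopf("word table not found: '%s'", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if ("closing" %in% names(tab)) tab$closing <- as.logical(tab$closing)
  if ("excluded" %in% names(tab)) tab$excluded <- as.logical(tab$excluded)
  tab
}

#' @rdname readWordTable
#' @param table a word-table `data.frame`.
#' @export
writeWordTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write recordings as JSON
#'
#' A self-contained JSON object with fields `fs`, `word_offsets`,
#' `word_table_ref` and `data` (channels x samples, nested arrays). Meant
#' for modest desk-scale recordings.
#'
#' @param path file path.
#' @return `readRecording()` returns a [Recording-class].
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stopf("recording not found: '%s'", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Recording",
    data = as.matrix(obj$data), fs = obj$fs,
    wordOffsets = as.numeric(obj$word_offsets),
    wordTableRef = as.character(obj$word_table_ref %||% "")
  )
}

#' @rdname readRecording
#' @param rec a [Recording-class].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  jsonlite::write_json(
    list(
      fs = rec@fs, word_offsets = rec@wordOffsets,
      word_table_ref = rec@wordTableRef, data = rec@data
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a gamma-mixture fit to JSON
#'
#' Fields `w`, `shape`, `rate`, `boundary`, `loglik`, `n_iter`,
#' `converged`.
#'
#' @param fit a [GammaMixtureFit-class].
#' @param path file path.
#' @export
writeMixtureFit <- function(fit, path) {
  stopifnot(is(fit, "GammaMixtureFit"))
  jsonlite::write_json(
    list(
      w = fit@w, shape = fit@shape, rate = fit@rate,
      boundary = fit@boundary, loglik = fit@loglik,
      n_iter = fit@nIter, converged = fit@converged
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname writeMixtureFit
#' @export
readMixtureFit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GammaMixtureFit",
    w = as.numeric(obj$w), shape = as.numeric(obj$shape),
    rate = as.numeric(obj$rate), loglik = as.numeric(obj$loglik),
    boundary = if (is.null(obj$boundary)) NA_real_ else as.numeric(obj$boundary),
    nIter = as.integer(obj$n_iter), converged = as.logical(obj$converged),
    loglikTrace = numeric(0)
  )
}

#' Serialize a split design to JSON
#'
#' @param split a [SplitDesign-class].
#' @param path file path.
#' @export
writeSplitDesign <- function(split, path) {
  stopifnot(is(split, "SplitDesign"))
  jsonlite::write_json(
    list(
      train_ids = split@trainIds,
      test_neutral = split@testNeutral,
      test_coherent = split@testCoherent,
      test_incoherent = split@testIncoherent,
      class_counts = split@classCounts,
      test_size_per_class = split@testSizePerClass,
      seed = split@seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeSplitDesign
#' @export
readSplitDesign <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- as.matrix(obj$class_counts)
  dimnames(cc) <- list(
    c("neutral", "coherent", "incoherent"),
    c("closing", "nonclosing")
  )
  new("SplitDesign",
    trainIds = as.integer(obj$train_ids),
    testNeutral = as.integer(obj$test_neutral),
    testCoherent = as.integer(obj$test_coherent),
    testIncoherent = as.integer(obj$test_incoherent),
    classCounts = cc,
    testSizePerClass = as.integer(obj$test_size_per_class),
    seed = as.integer(obj$seed)
  )
}
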