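# Bracketed constituency trees: parsing, closing-node counting, and the
# token filters applied before the prosody-syntax analysis.

#' Bracketed constituency tree
#'
#' An ordered labeled tree read from PTB-style bracketed text. Terminals
#' appear in sentence order and each terminal has exactly one preterminal
#' parent (`"(NN dog)"`). The internal representation is a recursive list;
#' use [terminalsOf()], [closingNodeCounts()] and [formatBracketed()] to
#' work with it.
#'
#' @slot root recursive node list: nonterminals are
#'   `list(label =, children = list(...))`, terminals `list(word =)`.
#' @slot nTerminals number of terminals.
#' @export
setClass("ConstituencyTree", representation(root = "list", nTerminals = "integer"))

setValidity("ConstituencyTree", function(object) {
  n <- countTerminals(object@root)
  if (n != object@nTerminals) {
    return("'nTerminals' does not match the tree")
  }
  if (n < 1L) {
    return("tree must have at least one terminal")
  }
  TRUE
})

countTerminals <- function(node) {
  if (!is.null(node$word)) {
    return(1L)
  }
  sum(vapply(node$children, countTerminals, integer(1)))
}

setMethod("show", "ConstituencyTree", function(object) {
  cat(sprintf(
    "ConstituencyTree: root %s, %d terminal(s)\n  %s\n",
    object@root$label, object@nTerminals, formatBracketed(object)
  ))
})

#' Parse a PTB-style bracketed tree
#'
#' Reads one bracketed sentence, e.g.
#' `"(S (NP (DT the) (NN dog)) (VP (VBZ barks)))"`. Unbalanced parentheses,
#' empty input, trailing text and terminals lacking a preterminal parent
#' are errors reported with the character position.
#'
#' @param text a single bracketed tree string.
#' @return a [ConstituencyTree-class].
#' @examples
#' tr <- parseBracketed("(S (NP (DT the) (NN dog)) (VP (VBZ barks)))")
#' terminalsOf(tr)
#' closingNodeCounts(tr)
#' @export
parseBracketed <- function(text) {
  if (!is.character(text) || length(text) != 1L) stopf("'text' must be a single string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  skipWs <- function() {
    while (pos <= n && chars[pos] %in% c(" ", "\t")) pos <<- pos + 1L
  }
  readAtom <- function() {
    start <- pos
    while (pos <= n && !chars[pos] %in% c(" ", "\t", "(", ")")) pos <<- pos + 1L
    if (pos == start) stopf("parse error at position %d: expected a label or word", start)
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parseNode <- function() {
    skipWs()
    if (pos > n || chars[pos] != "(") {
      stopf("parse error at position %d: expected '('", pos)
    }
    pos <<- pos + 1L
    skipWs()
    label <- readAtom()
    children <- list()
    words <- character()
    repeat {
      skipWs()
      if (pos > n) stopf("parse error at position %d: unbalanced parentheses", pos)
      if (chars[pos] == ")") {
        pos <<- pos + 1L
        break
      }
      if (chars[pos] == "(") {
        children[[length(children) + 1L]] <- parseNode()
      } else {
        words <- c(words, readAtom())
      }
    }
    if (length(words) > 1L || (length(words) == 1L && length(children))) {
      stopf(
        "parse error at position %d: every terminal needs its own preterminal parent",
        pos
      )
    }
    if (length(words) == 1L) {
      return(list(label = label, children = list(list(word = words))))
    }
    if (!length(children)) {
      stopf("parse error at position %d: empty constituent '%s'", pos, label)
    }
    list(label = label, children = children)
  }

  skipWs()
  if (pos > n) stopf("parse error: empty input")
  root <- parseNode()
  skipWs()
  if (pos <= n) stopf("parse error at position %d: trailing text after the tree", pos)
  new("ConstituencyTree", root = root, nTerminals = countTerminals(root))
}

#' Serialize a tree to its normalized bracketed form
#'
#' Single spaces between siblings; parse -> format -> parse is the identity
#' on the normalized form.
#'
#' @param tree a [ConstituencyTree-class].
#' @return a bracketed string.
#' @export
formatBracketed <- function(tree) {
  stopifnot(is(tree, "ConstituencyTree"))
  fmt <- function(node) {
    if (!is.null(node$word)) {
      return(node$word)
    }
    paste0("(", node$label, " ", paste(vapply(node$children, fmt, character(1)),
      collapse = " "
    ), ")")
  }
  fmt(tree@root)
}

#' Terminal words of a tree, left to right
#'
#' @param tree a [ConstituencyTree-class].
#' @return character vector of terminals in sentence order.
#' @export
terminalsOf <- function(tree) {
  stopifnot(is(tree, "ConstituencyTree"))
  words <- character(0)
  walk <- function(node) {
    if (!is.null(node$word)) {
      words[[length(words) + 1L]] <<- node$word
      return(invisible())
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree@root)
  words
}

#' Count closing nodes per word
#'
#' For each terminal, the number of tree nodes (including its preterminal)
#' whose rightmost terminal is that word -- equivalently the run of closing
#' brackets after the word in the normalized bracketed string. Under a
#' bottom-up traversal these are the constituents the word closes; every
#' word closes at least its own preterminal, so counts are >= 1, and the
#' counts over a sentence sum to the number of nodes in the tree.
#'
#' @param tree a [ConstituencyTree-class].
#' @return an integer vector, one count per terminal.
#' @examples
#' closingNodeCounts(parseBracketed("(S (NN ok))")) # 2: NN and S
#' @export
closingNodeCounts <- function(tree) {
  stopifnot(is(tree, "ConstituencyTree"))
  counts <- integer(tree@nTerminals)
  idx <- 0L
  # returns the index of the node's rightmost terminal
  walk <- function(node) {
    if (!is.null(node$word)) {
      idx <<- idx + 1L
      return(idx)
    }
    right <- 0L
    for (ch in node$children) right <- walk(ch)
    counts[right] <<- counts[right] + 1L
    right
  }
  walk(tree@root)
  counts
}

#' Read bracketed trees from a file
#'
#' One sentence per line, UTF-8; blank lines are skipped.
#'
#' @param path file path.
#' @return a list of [ConstituencyTree-class] objects.
#' @export
readTrees <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lapply(which(nzchar(lines)), function(i) {
    tryCatch(parseBracketed(lines[i]), error = function(e) {
      stopf("line %d: %s", i, conditionMessage(e))
    })
  })
}

#' Label words by closing phrase boundaries and apply the token filters
#'
#' A word carries a closing phrase boundary iff it closes more than one
#' node (its preterminal plus at least one phrase); a word closing only its
#' own preterminal closes no phrase. Tokens are excluded -- flagged with a
#' reason and dropped from analysis tables -- when they are
#' out-of-dictionary (`oovMarker`), sentence-final (to avoid end-of-sentence
#' positional confounds), or have zero prosodic boundary strength. Counts
#' are computed on the full trees before any removal, so exclusion never
#' changes another word's label. The first applicable reason in the order
#' oov, sentence_final, zero_strength is recorded.
#'
#' @param tokens a `data.frame` with at least `word` and `sentence_id`
#'   columns (optionally `token_id`, `talk_id`, `onset_s`, `offset_s`),
#'   one row per token in corpus order.
#' @param counts closing-node counts aligned with `tokens` (e.g. from
#'   [closingNodeCounts()] applied per sentence).
#' @param strengths prosodic boundary strengths aligned with `tokens`.
#' @param oovMarker the out-of-dictionary token text (default `"<unk>"`).
#' @return the word table: `tokens` plus `closing_count`, `closing`,
#'   `strength`, `excluded` and `exclude_reason` columns.
#' @seealso [analysisTable()] to drop excluded rows.
#' @export
labelAndFilter <- function(tokens, counts, strengths, oovMarker = "<unk>") {
  n <- NROW(tokens)
  if (length(counts) != n || length(strengths) != n) {
    stopf(
      "tokens (%d), counts (%d) and strengths (%d) must be aligned by position",
      n, length(counts), length(strengths)
    )
  }
  if (!all(c("word", "sentence_id") %in% names(tokens))) {
    stopf("'tokens' must have 'word' and 'sentence_id' columns")
  }
  out <- as.data.frame(tokens, stringsAsFactors = FALSE)
  if (is.null(out$token_id)) out$token_id <- seq_len(n)
  out$closing_count <- as.integer(counts)
  out$closing <- counts > 1L
  out$strength <- strengths

  lastOfSentence <- !duplicated(out$sentence_id, fromLast = TRUE)
  reason <- rep(NA_character_, n)
  reason[out$strength == 0] <- "zero_strength"
  reason[lastOfSentence] <- "sentence_final"
  reason[out$word == oovMarker] <- "oov"
  out$excluded <- !is.na(reason)
  out$exclude_reason <- reason
  out$closing[out$excluded] <- NA
  out
}

#' Drop excluded tokens from a word table
#'
#' @param wordTable a table from [labelAndFilter()] (or any table with an
#'   `excluded` column).
#' @return the non-excluded rows.
#' @export
analysisTable <- function(wordTable) {
  if (is.null(wordTable$excluded)) {
    return(wordTable)
  }
  wordTable[!wordTable$excluded, , drop = FALSE]
}
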