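# Fixtures and independent oracles shared across the suite.

# Pairwise-enumeration AUC oracle: P(pos > neg) + 0.5 P(tie) over all pairs.
aucPairwise <- function(scores, y) {
  y <- as.logical(y)
  pos <- scores[y]
  neg <- scores[!y]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Closing-count oracle: run of ')' after each terminal in a bracket string.
bracketRunCounts <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  counts <- integer(0)
  i <- 1L
  while (i <= length(toks)) {
    if (!toks[i] %in% c("(", ")") && i < length(toks) && toks[i + 1L] == ")") {
      run <- 0L
      j <- i + 1L
      while (j <= length(toks) && toks[j] == ")") {
        run <- run + 1L
        j <- j + 1L
      }
      counts <- c(counts, run)
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  counts
}

# Random bracketed sentence with nWords terminals (valid preterminals).
randomTreeString <- function(nWords, labels = c("NP", "VP", "PP", "S", "ADJP")) {
  stopifnot(nWords >= 1)
  preterm <- function(i) sprintf("(%s w%d)", sample(c("NN", "VBZ", "DT", "IN"), 1), i)
  build <- function(idx) {
    if (length(idx) == 1L) {
      return(preterm(idx))
    }
    k <- sample(seq_len(min(3L, length(idx) - 1L)), 1) + 1L # 2..4 children
    splits <- sort(sample(seq_len(length(idx) - 1L), k - 1L))
    parts <- split(idx, cut(seq_along(idx), c(0, splits, length(idx))))
    kids <- vapply(parts, build, character(1))
    sprintf("(%s %s)", sample(labels, 1), paste(kids, collapse = " "))
  }
  sprintf("(S %s)", build(seq_len(nWords)))
}

# Count nodes (nonterminals + preterminals) in a bracket string.
bracketNodeCount <- function(s) lengths(regmatches(s, gregexpr("\\(", s)))

# A small labeled cohort ready for splitting/decoding.
smallLabeledCohort <- function(nSubjects = 2, nWords = 400, seed = 11, ...) {
  cfg <- synthConfig(nSubjects = nSubjects, nWords = nWords, seed = seed, ...)
  cohort <- genCohort(cfg)
  lab <- labelCohortProsody(cohort, seed = 1)
  for (i in seq_along(cohort)) cohort[[i]]$table <- lab$tables[[i]]
  list(cfg = cfg, cohort = cohort, fit = lab$fit)
}

# Deterministic toy table with fixed cell sizes (for split tests).
toyCellTable <- function(sizes = c(weak.no = 56, weak.yes = 44, strong.no = 28, strong.yes = 72)) {
  cells <- rep(names(sizes), sizes)
  pros <- sub("\\..*$", "", cells)
  closing <- sub("^.*\\.", "", cells) == "yes"
  data.frame(
    token_id = seq_along(cells),
    prosody_class = pros,
    closing = closing,
    strength = ifelse(pros == "strong", 2, 0.5),
    stringsAsFactors = FALSE
  )
}
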