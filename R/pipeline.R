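# End-to-end orchestration: synthesis (or file input) -> mixture fit ->
# syntax labels -> splits -> epochs/SVD -> decoding -> group statistics.

#' Assemble a pipeline configuration
#'
#' Either synthesizes a cohort (`synth` block) or loads word tables and
#' recordings from files. Exactly one data source must be configured. The
#' master seed is mandatory and drives every random draw downstream.
#'
#' @param synth a [SynthConfig-class] (or `NULL` when loading from files).
#' @param wordTablePaths,recordingPaths character vectors of per-subject
#'   file paths (TSV word tables, JSON recordings), used when `synth` is
#'   `NULL`.
#' @param treesPath optional path to bracketed trees (one sentence per
#'   line); when given, closing labels are recomputed from the trees via
#'   [labelAndFilter()] instead of taken from the word table.
#' @param seed master integer seed.
#' @param outDir output directory for the result bundle.
#' @param tmin,tmax epoch window in seconds.
#' @param windows named list of MVPA windows (default pre `[-0.4, 0)` and
#'   post `[0, 0.4)`).
#' @param C MVPA regularization parameter (default 1).
#' @param nFolds MVPA folds (default 10).
#' @param doTemporal run per-timepoint temporal decoding (default `TRUE`).
#' @param Cgrid,innerFolds temporal decoding settings.
#' @param nPerm permutation budget (default 2048).
#' @param alpha within-subject significance level for prevalence (default
#'   0.05).
#' @param svdCutoff SVD energy cutoff (default 0.99).
#' @param verbose print per-stage progress (default `TRUE`).
#' @return a `"prosynPipelineConfig"` list.
#' @export
pipelineConfig <- function(synth = synthConfig(), wordTablePaths = NULL,
                           recordingPaths = NULL, treesPath = NULL,
                           seed = 1, outDir = tempfile("prosyn-run-"),
                           tmin = -0.4, tmax = 0.8,
                           windows = list(pre = c(-0.4, 0), post = c(0, 0.4)),
                           C = 1, nFolds = 10,
                           doTemporal = TRUE, Cgrid = 10^seq(-5, 5),
                           innerFolds = 5, nPerm = 2048, alpha = 0.05,
                           svdCutoff = 0.99, verbose = TRUE) {
  if (is.null(seed)) stopf("a master seed is mandatory")
  hasFiles <- !is.null(wordTablePaths) || !is.null(recordingPaths)
  if (!is.null(synth) && hasFiles) {
    stopf("configure exactly one data source: a synthesis block or input paths")
  }
  if (is.null(synth)) {
    if (is.null(wordTablePaths) || is.null(recordingPaths)) {
      stopf("file input needs both 'wordTablePaths' and 'recordingPaths'")
    }
    if (length(wordTablePaths) != length(recordingPaths)) {
      stopf("'wordTablePaths' and 'recordingPaths' must align by subject")
    }
  }
  structure(
    list(
      synth = synth, wordTablePaths = wordTablePaths,
      recordingPaths = recordingPaths, treesPath = treesPath,
      seed = as.integer(seed), outDir = outDir, tmin = tmin, tmax = tmax,
      windows = windows, C = C, nFolds = nFolds, doTemporal = doTemporal,
      Cgrid = Cgrid, innerFolds = innerFolds, nPerm = nPerm, alpha = alpha,
      svdCutoff = svdCutoff, verbose = verbose
    ),
    class = "prosynPipelineConfig"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipelineConfig()]; a `synth` mapping
#' is passed to [synthConfig()].
#'
#' @param path YAML file path.
#' @return a `"prosynPipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$synth)) obj$synth <- do.call(synthConfig, obj$synth)
  if (!is.null(obj$windows)) obj$windows <- lapply(obj$windows, as.numeric)
  do.call(pipelineConfig, obj)
}

stageMsg <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Binarize a cohort's prosodic strengths at the fitted mixture boundary
#'
#' Fits the two-component gamma mixture to the pooled strengths of all
#' subjects' word tables (zero strengths removed first) and attaches a
#' `prosody_class` column to each table using the fitted boundary.
#'
#' @param cohort a list of `list(table =, recording =)` pairs, as from
#'   [genCohort()].
#' @param seed seed for the EM restarts.
#' @return a list with `tables` (labeled word tables) and `fit`
#'   ([GammaMixtureFit-class]).
#' @export
labelCohortProsody <- function(cohort, seed = 1) {
  tables <- lapply(cohort, `[[`, "table")
  strengths <- unlist(lapply(tables, function(t) t$strength))
  fit <- fitGammaMixture(strengths[strengths > 0], seed = seed)
  if (is.na(fit@boundary)) stopf("mixture fit is degenerate: no binarization boundary")
  tables <- lapply(tables, function(t) {
    t <- t[t$strength > 0, , drop = FALSE]
    t$prosody_class <- as.character(classifyStrength(t$strength, fit@boundary))
    t
  })
  list(tables = tables, fit = fit)
}

#' Prepare one subject's decoding inputs
#'
#' Builds the split, extracts word-offset epochs, fits the SVD reduction on
#' training epochs only, projects all epochs, and assembles the reduced
#' training pool plus the three test sets. The 100 ms discard rule can
#' unbalance the surviving training pool, so exact class balance is
#' restored by downsampling the majority class.
#'
#' @param table a labeled word table with `token_id`, `offset_s`,
#'   `closing` and `prosody_class` columns.
#' @param rec the subject's [Recording-class].
#' @param tmin,tmax epoch window in seconds.
#' @param svdCutoff SVD energy cutoff.
#' @param splitSeed,balanceSeed RNG seeds for the split draw and the
#'   rebalancing draw.
#' @return a list with `train` ([EpochSet-class]), `tests` (named list of
#'   [EpochSet-class]), `split`, `reduction`.
#' @export
prepareSubject <- function(table, rec, tmin = -0.4, tmax = 0.8,
                           svdCutoff = 0.99, splitSeed = 1, balanceSeed = 2) {
  split <- buildSplit(table, seed = splitSeed)

  es <- extractEpochs(rec,
    offsets = table$offset_s, tmin = tmin, tmax = tmax,
    ids = table$token_id, labels = table$closing
  )
  red <- fitSvdReduction(epochsForIds(es, intersect(trainIds(split), tokenIds(es))),
    cutoff = svdCutoff
  )
  esR <- applyReduction(es, red)
  pickMulti <- function(ids) ids[ids %in% tokenIds(esR)]

  trIds <- intersect(trainIds(split), tokenIds(esR))
  trLab <- table$closing[match(trIds, table$token_id)]
  k <- min(sum(trLab), sum(!trLab))
  trIds <- withSeed(balanceSeed, {
    pos <- trIds[trLab]
    neg <- trIds[!trLab]
    c(
      if (length(pos) > k) sample(pos, k) else pos,
      if (length(neg) > k) sample(neg, k) else neg
    )
  })
  list(
    train = epochsForIds(esR, trIds),
    tests = list(
      neutral = epochsForIds(esR, pickMulti(testIds(split, "neutral"))),
      coherent = epochsForIds(esR, pickMulti(testIds(split, "coherent"))),
      incoherent = epochsForIds(esR, pickMulti(testIds(split, "incoherent")))
    ),
    split = split, reduction = red
  )
}

# Decode one subject: prepare -> MVPA (+temporal).
decodeSubject <- function(table, rec, cfg, subjectIdx) {
  prep <- prepareSubject(table, rec,
    tmin = cfg$tmin, tmax = cfg$tmax, svdCutoff = cfg$svdCutoff,
    splitSeed = deriveSeed(cfg$seed, 3L, subjectIdx),
    balanceSeed = deriveSeed(cfg$seed, 9L, subjectIdx)
  )
  train <- prep$train
  tests <- prep$tests

  mvpa <- lapply(names(cfg$windows), function(wn) {
    mvpaDecode(train, tests,
      window = cfg$windows[[wn]], C = cfg$C, nFolds = cfg$nFolds,
      seed = deriveSeed(cfg$seed, 4L, subjectIdx)
    )
  })
  names(mvpa) <- names(cfg$windows)

  temporal <- NULL
  if (isTRUE(cfg$doTemporal)) {
    temporal <- temporalDecode(train, tests,
      Cgrid = cfg$Cgrid, innerFolds = cfg$innerFolds,
      seed = deriveSeed(cfg$seed, 5L, subjectIdx)
    )
  }
  list(
    split = prep$split, reduction = prep$reduction,
    mvpa = mvpa, temporal = temporal
  )
}

groupStatistics <- function(subjectResults, cfg) {
  conds <- c("neutral", "coherent", "incoherent")
  winNames <- names(cfg$windows)

  mvpaLong <- do.call(rbind, lapply(seq_along(subjectResults), function(i) {
    do.call(rbind, lapply(winNames, function(wn) {
      m <- subjectResults[[i]]$mvpa[[wn]]
      data.frame(
        subject = i, window = wn, condition = names(m$meanAuc),
        auc = as.numeric(m$meanAuc), stringsAsFactors = FALSE
      )
    }))
  }))

  stats <- list()
  for (wn in winNames) {
    sub <- mvpaLong[mvpaLong$window == wn, ]
    aucMat <- sapply(conds, function(cn) sub$auc[sub$condition == cn][order(sub$subject[sub$condition == cn])])

    vsChance <- lapply(conds, function(cn) {
      pairedPermutationTest(aucMat[, cn], 0.5,
        nPerm = cfg$nPerm, side = "greater",
        seed = deriveSeed(cfg$seed, 6L, 1L)
      )
    })
    names(vsChance) <- conds
    pAdj <- holmAdjust(vapply(vsChance, `[[`, numeric(1), "p"))

    contrasts <- list(
      coherent_vs_incoherent = pairedPermutationTest(
        aucMat[, "coherent"], aucMat[, "incoherent"],
        nPerm = cfg$nPerm, side = "greater", seed = deriveSeed(cfg$seed, 6L, 2L)
      ),
      coherent_vs_neutral = pairedPermutationTest(
        aucMat[, "coherent"], aucMat[, "neutral"],
        nPerm = cfg$nPerm, side = "greater", seed = deriveSeed(cfg$seed, 6L, 3L)
      )
    )
    contrastAdj <- holmAdjust(vapply(contrasts, `[[`, numeric(1), "p"))

    # within-subject significance for prevalence: one-sided t test of the
    # per-fold AUCs against chance at the configured alpha
    prevalence <- lapply(conds, function(cn) {
      sig <- vapply(subjectResults, function(sr) {
        folds <- sr$mvpa[[wn]]$aucs
        fa <- folds$auc[folds$condition == cn]
        if (sd(fa) < 1e-12) {
          mean(fa) > 0.5
        } else {
          t.test(fa, mu = 0.5, alternative = "greater")$p.value < cfg$alpha
        }
      }, logical(1))
      prevalenceEstimate(sum(sig), length(sig), alpha = cfg$alpha)
    })
    names(prevalence) <- conds

    stats[[wn]] <- list(
      meanAuc = colMeans(aucMat), vsChance = vsChance, pHolm = pAdj,
      contrasts = contrasts, contrastPHolm = contrastAdj,
      prevalence = prevalence
    )
  }

  clusters <- NULL
  if (!is.null(subjectResults[[1]]$temporal)) {
    times <- subjectResults[[1]]$temporal$times
    tempResults <- lapply(subjectResults, `[[`, "temporal")
    clusters <- list()
    for (cn in conds) {
      m <- temporalAucMatrix(tempResults, cn)
      clusters[[cn]] <- clusterPermutationTest(m - 0.5,
        times = times,
        nPerm = cfg$nPerm, seed = deriveSeed(cfg$seed, 7L, 1L)
      )
    }
    mc <- temporalAucMatrix(tempResults, "coherent")
    clusters$coherent_vs_incoherent <- clusterPermutationTest(
      mc - temporalAucMatrix(tempResults, "incoherent"),
      times = times, nPerm = cfg$nPerm, seed = deriveSeed(cfg$seed, 7L, 2L)
    )
    clusters$coherent_vs_neutral <- clusterPermutationTest(
      mc - temporalAucMatrix(tempResults, "neutral"),
      times = times, nPerm = cfg$nPerm, seed = deriveSeed(cfg$seed, 7L, 3L)
    )
  }

  list(mvpaLong = mvpaLong, windows = stats, clusters = clusters)
}

permTestJson <- function(pt) {
  list(statistic = pt$statistic, p = pt$p, n_perm = pt$nPerm, exhaustive = pt$exhaustive, side = pt$side)
}

clusterJson <- function(ct) {
  list(
    threshold = ct$threshold, n_perm = ct$nPerm, exhaustive = ct$exhaustive,
    clusters = ct$clusters
  )
}

#' Run the full analysis pipeline
#'
#' Stages: synthesize or load the cohort; fit the gamma mixture to the
#' pooled strengths and binarize at the boundary; test the stimulus-level
#' association; build per-subject splits; epoch, reduce and decode each
#' subject; run the group statistics; and write a machine-readable bundle
#' (JSON + CSV) plus a manifest to the output directory. Given the same
#' configuration and seed, the result bundle is byte-identical across
#' runs.
#'
#' @param cfg a `"prosynPipelineConfig"` from [pipelineConfig()] or a path
#'   to a YAML file for [readPipelineConfig()].
#' @return (invisibly) a list with the in-memory results: `wordTables`,
#'   `mixtureFit`, `association`, `subjects`, `group`, `outDir`.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  stopifnot(inherits(cfg, "prosynPipelineConfig"))

  # ---- stage: data ----
  if (!is.null(cfg$synth)) {
    stageMsg(cfg, "stage synth: generating %d-subject cohort", cfg$synth@nSubjects)
    cohort <- withStage("synth", genCohort(cfg$synth))
  } else {
    stageMsg(cfg, "stage load: reading %d subject(s)", length(cfg$wordTablePaths))
    cohort <- withStage("load", {
      lapply(seq_along(cfg$wordTablePaths), function(i) {
        list(
          table = readWordTable(cfg$wordTablePaths[i]),
          recording = readRecording(cfg$recordingPaths[i])
        )
      })
    })
  }
  tables <- lapply(cohort, `[[`, "table")

  # ---- stage: syntax (optional tree-based relabeling) ----
  if (!is.null(cfg$treesPath)) {
    stageMsg(cfg, "stage syntax: labeling from %s", cfg$treesPath)
    tables <- withStage("syntax", {
      trees <- readTrees(cfg$treesPath)
      counts <- unlist(lapply(trees, closingNodeCounts))
      lapply(tables, function(tab) {
        labeled <- labelAndFilter(tab, counts, tab$strength)
        labeled
      })
    })
  }

  # ---- stage: prosody ----
  stageMsg(cfg, "stage prosody: fitting the strength mixture")
  fitRes <- withStage("prosody", {
    lab <- labelCohortProsody(
      lapply(seq_along(tables), function(i) list(table = tables[[i]])),
      seed = deriveSeed(cfg$seed, 8L, 1L)
    )
    assoc <- testAssociation(
      do.call(rbind, lapply(lab$tables, function(t) t[, c("strength", "closing")])),
      unlist(lapply(lab$tables, function(t) t$prosody_class))
    )
    list(fit = lab$fit, tables = lab$tables, assoc = assoc)
  })
  tables <- fitRes$tables

  # ---- stage: decode ----
  subjects <- lapply(seq_along(tables), function(i) {
    stageMsg(cfg, "stage decode: subject %d/%d", i, length(tables))
    withStage(
      sprintf("decode[subject %d]", i),
      decodeSubject(tables[[i]], cohort[[i]]$recording, cfg, i)
    )
  })

  # ---- stage: stats ----
  stageMsg(cfg, "stage stats: group-level inference")
  group <- withStage("stats", groupStatistics(subjects, cfg))

  # ---- stage: write ----
  outDir <- cfg$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  withStage("write", {
    writeMixtureFit(fitRes$fit, file.path(outDir, "mixture_fit.json"))
    jsonlite::write_json(
      list(
        binomial_z = fitRes$assoc$binomialZ, binomial_p = fitRes$assoc$binomialP,
        gamma_glm_t = fitRes$assoc$gammaGlmT, gamma_glm_p = fitRes$assoc$gammaGlmP,
        contingency = as.data.frame(fitRes$assoc$contingency)
      ),
      file.path(outDir, "association.json"),
      auto_unbox = TRUE, digits = NA
    )
    write.table(group$mvpaLong, file.path(outDir, "mvpa_auc.csv"),
      sep = ",", row.names = FALSE, quote = FALSE
    )
    if (isTRUE(cfg$doTemporal)) {
      tempLong <- do.call(rbind, lapply(seq_along(subjects), function(i) {
        cbind(subject = i, subjects[[i]]$temporal$aucs)
      }))
      write.table(tempLong, file.path(outDir, "temporal_auc.csv"),
        sep = ",", row.names = FALSE, quote = FALSE
      )
    }
    groupJson <- list(
      windows = lapply(group$windows, function(w) {
        list(
          mean_auc = as.list(w$meanAuc),
          vs_chance = lapply(w$vsChance, permTestJson),
          p_holm = as.list(w$pHolm),
          contrasts = lapply(w$contrasts, permTestJson),
          contrast_p_holm = as.list(w$contrastPHolm),
          prevalence = lapply(w$prevalence, function(p) {
            list(k = p$k, n = p$n, map = p$map, hpdi = p$hpdi)
          })
        )
      }),
      clusters = if (!is.null(group$clusters)) lapply(group$clusters, clusterJson)
    )
    jsonlite::write_json(groupJson, file.path(outDir, "group_stats.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    manifest <- list(
      package_version = as.character(utils::packageVersion("prosyn")),
      seed = cfg$seed,
      config = configManifest(cfg)
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  })
  stageMsg(cfg, "done: results in %s", outDir)

  invisible(list(
    wordTables = tables, mixtureFit = fitRes$fit, association = fitRes$assoc,
    subjects = subjects, group = group, outDir = outDir
  ))
}

# Config echo for the manifest: every number needed to reproduce the bundle.
configManifest <- function(cfg) {
  syn <- NULL
  if (!is.null(cfg$synth)) {
    s <- cfg$synth
    syn <- list(
      n_subjects = s@nSubjects, n_words = s@nWords,
      gamma1_shape = s@gamma1Shape, gamma1_rate = s@gamma1Rate,
      gamma2_shape = s@gamma2Shape, gamma2_rate = s@gamma2Rate,
      w_strong = s@wStrong,
      p_closing_given_strong = s@pClosingGivenStrong,
      p_closing_given_weak = s@pClosingGivenWeak,
      n_channels = s@nChannels, fs = s@fs,
      gain_coherent = s@gainCoherent, gain_neutral = s@gainNeutral,
      gain_incoherent = s@gainIncoherent, pre_gain = s@preGain,
      noise_sd = s@noiseSd, short_gap_fraction = s@shortGapFraction,
      seed = s@seed
    )
  }
  list(
    synth = syn,
    word_table_paths = cfg$wordTablePaths, recording_paths = cfg$recordingPaths,
    trees_path = cfg$treesPath, tmin = cfg$tmin, tmax = cfg$tmax,
    windows = cfg$windows, C = cfg$C, n_folds = cfg$nFolds,
    do_temporal = cfg$doTemporal, c_grid = cfg$Cgrid,
    inner_folds = cfg$innerFolds, n_perm = cfg$nPerm, alpha = cfg$alpha,
    svd_cutoff = cfg$svdCutoff
  )
}
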