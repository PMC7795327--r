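# Experiment runner for the three-experiment protocol: negative-class
# durations fixed (FD) or Burr variable (VD) independently in training
# and test, crossed with three tasks (3-class, crackles-vs-other,
# wheezes-vs-other), repeated over seeds.

#' Experiment configuration
#'
#' @param trainMode,testMode negative-event mode per split:
#'   `"fixed"` (50/150 ms) or `"variable"` (Burr-distributed durations).
#' @param task `"3class"`, `"2class_crackles"` or `"2class_wheezes"`.
#' @param featureSubset `"10MRMR"`, `"100MRMR"` or `"full"` (classical
#'   classifiers only).
#' @param classifier `"lda"`, `"svm_rbf"`, `"rusboost"`, `"duration"`
#'   (duration-only ablation), `"cnn_dual"`, `"cnn_spec"` or `"cnn_mel"`.
#' @param seeds integer vector of training seeds.
#' @return object of class `ExperimentConfig`.
#' @export
experimentConfig <- function(trainMode = c("fixed", "variable"),
                             testMode = c("fixed", "variable"),
                             task = c(
                               "3class", "2class_crackles", "2class_wheezes"
                             ),
                             featureSubset = c("100MRMR", "10MRMR", "full"),
                             classifier = "lda", seeds = 0:9) {
  structure(
    list(
      trainMode = match.arg(trainMode), testMode = match.arg(testMode),
      task = match.arg(task), featureSubset = match.arg(featureSubset),
      classifier = classifier, seeds = unique(as.integer(seeds))
    ),
    class = "ExperimentConfig"
  )
}

# Map raw event labels onto task classes; NA = event not in the task.
taskClass <- function(labels, task, mode) {
  out <- rep(NA_character_, length(labels))
  if (task == "3class") {
    out[labels == "crackle"] <- "crackle"
    out[labels == "wheeze"] <- "wheeze"
    neg <- if (mode == "fixed") {
      c("other50", "other150")
    } else {
      c("otherCrackle", "otherWheeze")
    }
    out[labels %in% neg] <- "other"
  } else if (task == "2class_crackles") {
    out[labels == "crackle"] <- "crackle"
    out[labels == (if (mode == "fixed") "other50" else "otherCrackle")] <-
      "other"
  } else {
    out[labels == "wheeze"] <- "wheeze"
    out[labels == (if (mode == "fixed") "other150" else "otherWheeze")] <-
      "other"
  }
  out
}

#' Assemble the event set of one split
#'
#' Annotated events plus the negative events of the requested mode,
#' generated per recording with predetermined per-file streams derived
#' from `rgeSeed`.
#'
#' @param manifest a [DatasetManifest-class] with in-memory recordings.
#' @param mode `"fixed"` or `"variable"`.
#' @param rgeSeed master seed for negative-event generation.
#' @param fixedCounts counts per fixed duration (see [generateFixedRge()]).
#' @param nCrackleLike,nWheezeLike variable-mode counts per recording.
#' @return data.frame with recordingId, start, end, label, duration.
#' @export
assembleEvents <- function(manifest, mode = c("fixed", "variable"),
                           rgeSeed = 99,
                           fixedCounts = c("0.05" = 3, "0.15" = 2),
                           nCrackleLike = 3, nWheezeLike = 2) {
  mode <- match.arg(mode)
  recs <- manifestRecordings(manifest)
  rows <- lapply(names(recs), function(id) {
    rec <- recs[[id]]$recording
    ars <- recs[[id]]$events
    rge <- if (mode == "fixed") {
      generateFixedRge(rec, ars, fixedCounts, rgeSeed)
    } else {
      generateVariableRge(rec, ars, nCrackleLike, nWheezeLike, seed = rgeSeed)
    }
    ev <- rbind(ars, rge)
    if (!nrow(ev)) {
      return(NULL)
    }
    data.frame(recordingId = id, ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$duration <- out$end - out$start
  out
}

# Stable cache key for one excerpt's features.
eventKey <- function(recordingId, start, end, tag) {
  sprintf("%s|%.6f|%.6f|%s", recordingId, start, end, tag)
}

#' Extract (cached) feature vectors for an event table
#'
#' @param manifest a [DatasetManifest-class] with in-memory recordings.
#' @param events data.frame from [assembleEvents()].
#' @param windows feature window lengths in milliseconds.
#' @param cache optional environment reused across calls to avoid
#'   re-extracting shared events.
#' @param policy an [excerptPolicy()].
#' @return numeric matrix, one row per event.
#' @export
eventFeatureMatrix <- function(manifest, events, windows = c(32, 128),
                               cache = NULL, policy = excerptPolicy()) {
  recs <- manifestRecordings(manifest)
  tag <- paste(windows, collapse = "-")
  out <- matrix(
    NA_real_, nrow(events), 405L * length(windows),
    dimnames = list(NULL, featureVectorNames(windows))
  )
  for (i in seq_len(nrow(events))) {
    key <- eventKey(
      events$recordingId[i], events$start[i], events$end[i], tag
    )
    v <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      rec <- recs[[events$recordingId[i]]]$recording
      wave <- excerptEvent(rec, events[i, ], policy)
      vv <- extractFeatureVector(wave, rate(rec), windows)
      if (!is.null(cache)) cache[[key]] <- vv
      vv
    }
    out[i, ] <- v
  }
  out
}

#' Compute (cached) CNN input images for an event table
#'
#' @inheritParams eventFeatureMatrix
#' @param cfg [stftConfig()] for the image spectrogram.
#' @param nMels mel bands for the mel branch.
#' @return list with `spec` and `mel` arrays (see [stackImages()]).
#' @export
eventImageArrays <- function(manifest, events, cfg = stftConfig(),
                             nMels = 64, cache = NULL,
                             policy = excerptPolicy()) {
  recs <- manifestRecordings(manifest)
  tag <- sprintf("img|%s|%d|%d", cfg$windowKind, cfg$nFft, nMels)
  imgs <- lapply(seq_len(nrow(events)), function(i) {
    key <- eventKey(
      events$recordingId[i], events$start[i], events$end[i], tag
    )
    if (!is.null(cache) && !is.null(cache[[key]])) {
      return(cache[[key]])
    }
    rec <- recs[[events$recordingId[i]]]$recording
    wave <- excerptEvent(rec, events[i, ], policy)
    im <- eventImages(wave, cfg, rate(rec), nMels)
    if (!is.null(cache)) cache[[key]] <- im
    im
  })
  list(
    spec = stackImages(lapply(imgs, `[[`, "spec")),
    mel = stackImages(lapply(imgs, `[[`, "mel"))
  )
}

cnnBranchInputs <- function(classifier, arrays) {
  switch(classifier,
    cnn_dual = list(arrays$spec, arrays$mel),
    cnn_spec = list(arrays$spec),
    cnn_mel = list(arrays$mel),
    stop("unknown CNN classifier id: ", classifier)
  )
}

#' Run one experiment
#'
#' Builds the task's event sets (annotated events plus the configured
#' negative mode per split), extracts features or images, selects
#' features on the training split only, trains one model per seed and
#' evaluates on the test split. Returns per-seed metrics, their
#' mean/std summary and per-seed confusion matrices.
#'
#' @param cfg an [experimentConfig()].
#' @param trainManifest,testManifest participant-disjoint
#'   [DatasetManifest-class] objects.
#' @param windows feature windows (ms) for classical classifiers.
#' @param rgeSeed master seed for negative-event generation.
#' @param fixedCounts,nCrackleLike,nWheezeLike negative-event budget per
#'   recording (see [assembleEvents()]).
#' @param budget hyperparameter-search evaluations per seed.
#' @param cache optional environment for feature/image caching.
#' @param cnnOptions list for CNN classifiers: `cfg` ([stftConfig()]),
#'   `nMels`, `filters`, `dense`, `protocol` overrides (epochs, batch,
#'   lr, patience).
#' @return object of class `ExperimentReport`.
#' @export
runExperiment <- function(cfg, trainManifest, testManifest,
                          windows = c(32, 128), rgeSeed = 99,
                          fixedCounts = c("0.05" = 3, "0.15" = 2),
                          nCrackleLike = 3, nWheezeLike = 2,
                          budget = 8, cache = NULL, cnnOptions = list()) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  common <- length(intersect(
    unique(manifestParticipants(trainManifest)),
    unique(manifestParticipants(testManifest))
  ))
  if (common > 0L) stop("train and test manifests share participants")

  trEv <- assembleEvents(
    trainManifest, cfg$trainMode, rgeSeed, fixedCounts,
    nCrackleLike, nWheezeLike
  )
  teEv <- assembleEvents(
    testManifest, cfg$testMode, rgeSeed, fixedCounts,
    nCrackleLike, nWheezeLike
  )
  trEv$class <- taskClass(trEv$label, cfg$task, cfg$trainMode)
  teEv$class <- taskClass(teEv$label, cfg$task, cfg$testMode)
  trEv <- trEv[!is.na(trEv$class), , drop = FALSE]
  teEv <- teEv[!is.na(teEv$class), , drop = FALSE]
  classes <- if (cfg$task == "3class") {
    c("crackle", "wheeze", "other")
  } else if (cfg$task == "2class_crackles") {
    c("crackle", "other")
  } else {
    c("wheeze", "other")
  }
  if (!all(classes %in% trEv$class) || !all(classes %in% teEv$class)) {
    stop("a task class is absent from a split")
  }
  yTr <- factor(trEv$class, levels = classes)
  yTe <- factor(teEv$class, levels = classes)
  isCnn <- grepl("^cnn_", cfg$classifier)

  if (cfg$classifier == "duration") {
    xTr <- matrix(trEv$duration, dimnames = list(NULL, "duration"))
    xTe <- matrix(teEv$duration, dimnames = list(NULL, "duration"))
  } else if (isCnn) {
    imCfg <- cnnOptions$cfg
    if (is.null(imCfg)) imCfg <- stftConfig()
    nMels <- if (is.null(cnnOptions$nMels)) 64 else cnnOptions$nMels
    arrTr <- eventImageArrays(trainManifest, trEv, imCfg, nMels, cache)
    arrTe <- eventImageArrays(testManifest, teEv, imCfg, nMels, cache)
    xsTr <- cnnBranchInputs(cfg$classifier, arrTr)
    xsTe <- cnnBranchInputs(cfg$classifier, arrTe)
  } else {
    xTr <- eventFeatureMatrix(trainManifest, trEv, windows, cache)
    xTe <- eventFeatureMatrix(testManifest, teEv, windows, cache)
    if (cfg$featureSubset != "full") {
      k <- if (cfg$featureSubset == "10MRMR") 10L else 100L
      k <- min(k, ncol(xTr))
      ranking <- mrmrRank(xTr, yTr, maxRank = k)
      sel <- selectSubset(ranking, k)
      xTr <- xTr[, sel, drop = FALSE]
      xTe <- xTe[, sel, drop = FALSE]
    }
  }

  perSeed <- list()
  confusions <- list()
  binary <- cfg$task != "3class"
  positive <- classes[1]
  for (seed in cfg$seeds) {
    if (isCnn) {
      branches <- lapply(xsTr, function(a) dim(a)[2:3])
      spec <- cnnSpec(
        branches,
        filters = if (is.null(cnnOptions$filters)) {
          c(16, 32, 64)
        } else {
          cnnOptions$filters
        },
        dense = if (is.null(cnnOptions$dense)) 64 else cnnOptions$dense,
        nClasses = length(classes)
      )
      proto <- trainProtocol(
        epochs = if (is.null(cnnOptions$epochs)) 30 else cnnOptions$epochs,
        batch = if (is.null(cnnOptions$batch)) 16 else cnnOptions$batch,
        lr = if (is.null(cnnOptions$lr)) 0.001 else cnnOptions$lr,
        patience = if (is.null(cnnOptions$patience)) {
          10
        } else {
          cnnOptions$patience
        },
        seed = seed
      )
      model <- trainCnn(buildCnn(spec, seed), xsTr, yTr, proto)
      pred <- predictCnn(model, xsTe)
    } else if (cfg$classifier == "duration") {
      model <- trainClassifier("duration", xTr, yTr, list())
      model$classes <- classes
      pred <- predict(model, xTe)
    } else {
      model <- optimizeAndFit(
        cfg$classifier, xTr, yTr,
        budget = budget, seed = seed
      )
      pred <- predict(model, xTe)
    }
    cm <- confusionMatrix(yTe, pred$labels, levels = classes)
    confusions[[as.character(seed)]] <- cm
    row <- list(seed = seed, accuracy = overallAccuracy(cm))
    for (cl in classes) {
      m <- metricsFromConfusion(cm, cl)
      row[[paste0("f1_", cl)]] <- m[["f1"]]
      row[[paste0("mcc_", cl)]] <- m[["mcc"]]
    }
    if (binary) {
      sc <- pred$probs[, positive]
      row$auc <- aucBinary(sc, yTe == positive)
    }
    perSeed[[length(perSeed) + 1L]] <- as.data.frame(row)
  }
  perSeed <- do.call(rbind, perSeed)
  metricCols <- setdiff(names(perSeed), "seed")
  summary <- data.frame(
    metric = metricCols,
    mean = vapply(metricCols, function(cn) mean(perSeed[[cn]]), 0),
    sd = vapply(metricCols, function(cn) {
      if (nrow(perSeed) > 1L) stats::sd(perSeed[[cn]]) else 0
    }, 0),
    row.names = NULL
  )
  structure(
    list(
      config = cfg, classes = classes, perSeed = perSeed,
      summary = summary, confusions = confusions,
      eventCounts = list(
        train = table(yTr), test = table(yTe),
        trainLabels = countEventsByClass(trEv),
        testLabels = countEventsByClass(teEv)
      )
    ),
    class = "ExperimentReport"
  )
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Task %s | train %s / test %s | %s (%s) | %d seed(s)\n",
    cfg$task, cfg$trainMode, cfg$testMode, cfg$classifier,
    cfg$featureSubset, length(cfg$seeds)
  ))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-16s %5.1f ± %4.1f\n", s$metric[i],
      100 * s$mean[i], 100 * s$sd[i]
    ))
  }
  invisible(x)
}

#' Mean accuracy of a report
#'
#' @param report an [runExperiment()] result.
#' @return mean overall accuracy over seeds.
#' @export
reportAccuracy <- function(report) {
  stopifnot(inherits(report, "ExperimentReport"))
  report$summary$mean[report$summary$metric == "accuracy"]
}
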