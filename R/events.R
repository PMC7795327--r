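# Negative-event generation and event excerpting.
#
# The negative ("other") class is created in two modes:
#  * fixed:   events of exactly 50 ms and 150 ms, the classical design that
#             lets classifiers shortcut on duration;
#  * variable: durations drawn from Burr XII fits of the annotated event
#             durations, so duration carries (almost) no class information.

#' Event excerpt policy
#'
#' Every event is turned into an excerpt of at most `maxLen` seconds:
#' shorter events are centered and zero-padded to `maxLen`, events longer
#' than `maxLen` are cut to their first `maxLen` seconds. The default 2 s
#' ceiling comes from Median + 2 SD of annotated wheeze durations.
#'
#' @param maxLen maximum excerpt length in seconds.
#' @return an object of class `ExcerptPolicy`.
#' @export
excerptPolicy <- function(maxLen = 2) {
  if (!is.finite(maxLen) || maxLen <= 0) stop("maxLen must be positive")
  structure(list(maxLen = maxLen), class = "ExcerptPolicy")
}

# Place n events of given durations uniformly over the feasible range,
# optionally forbidding overlap with `keepOut` intervals (matrix with
# columns start, end) and with one another. Longest events are placed
# first (better packing); bounded retries per event.
placeEvents <- function(recDuration, durations, keepOut = NULL,
                        maxTries = 500L) {
  n <- length(durations)
  placed <- matrix(numeric(0), ncol = 2)
  if (!is.null(keepOut) && nrow(keepOut)) {
    placed <- keepOut
  }
  ord <- order(durations, decreasing = TRUE)
  starts <- numeric(n)
  for (i in ord) {
    d <- durations[i]
    if (d >= recDuration) {
      stop(sprintf(
        "event duration %.3f s does not fit in a %.3f s recording",
        d, recDuration
      ))
    }
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      s <- stats::runif(1, 0, recDuration - d)
      if (!nrow(placed) ||
        all(s + d <= placed[, 1] | s >= placed[, 2])) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place event without overlap after bounded retries")
    }
    placed <- rbind(placed, c(s, s + d))
    starts[i] <- s
  }
  starts
}

#' Generate fixed-duration negative events
#'
#' Random events of exactly 50 ms and 150 ms (labels `other50`,
#' `other150`), placed uniformly over the recording. By default they may
#' not overlap annotated events or each other, keeping the negative class
#' pure. The random stream is derived from `(seed, recordingId)`, so each
#' file gets its own predetermined stream.
#'
#' @param rec an [AudioRecording-class].
#' @param ars data.frame of annotated events (start, end, label).
#' @param counts named numeric vector: requested event count per duration
#'   in seconds, e.g. `c("0.05" = 3, "0.15" = 2)`.
#' @param seed master integer seed.
#' @param avoidOverlap forbid overlap with `ars` and among generated events.
#' @return data.frame of generated events (start, end, label).
#' @export
generateFixedRge <- function(rec, ars, counts = c("0.05" = 3, "0.15" = 2),
                             seed = 1, avoidOverlap = TRUE) {
  checkEvents(ars)
  durs <- as.numeric(names(counts))
  if (anyNA(durs) || any(durs <= 0)) {
    stop("counts must be named by positive durations in seconds")
  }
  if (duration(rec) <= max(durs)) {
    stop("recording shorter than the largest requested duration")
  }
  allDur <- rep(durs, times = counts)
  lab <- rep(
    ifelse(abs(durs - 0.05) < 1e-9, "other50",
      ifelse(abs(durs - 0.15) < 1e-9, "other150",
        sprintf("other%d", round(durs * 1000))
      )
    ),
    times = counts
  )
  keep <- if (avoidOverlap && nrow(ars)) {
    cbind(ars$start, ars$end)
  }
  withSeed(deriveSeed(seed, recordingId(rec)), {
    starts <- placeEvents(duration(rec), allDur, keep)
    out <- data.frame(
      start = starts, end = starts + allDur, label = lab,
      stringsAsFactors = FALSE
    )
    out[order(out$start), , drop = FALSE]
  })
}

#' Generate variable-duration negative events
#'
#' Negative events whose durations are drawn from truncated Burr XII
#' models: `otherCrackle` (crackle-duration-like, <= 100 ms) and
#' `otherWheeze` (wheeze-duration-like, 100 ms to 2 s). Placement and
#' per-file seeding as in [generateFixedRge()].
#'
#' @param rec an [AudioRecording-class].
#' @param ars data.frame of annotated events.
#' @param nCrackleLike,nWheezeLike event counts per model.
#' @param models list with elements `crackle` and `wheeze`
#'   ([burrParams()] objects).
#' @param seed master integer seed.
#' @param avoidOverlap forbid overlap with `ars` and among generated events.
#' @return data.frame of generated events (start, end, label).
#' @export
generateVariableRge <- function(rec, ars, nCrackleLike = 3, nWheezeLike = 1,
                                models = list(
                                  crackle = burrOtherCrackle(),
                                  wheeze = burrOtherWheeze()
                                ),
                                seed = 1, avoidOverlap = TRUE) {
  checkEvents(ars)
  recSeed <- deriveSeed(seed, recordingId(rec))
  dC <- sampleDurations(models$crackle, nCrackleLike, recSeed)
  dW <- sampleDurations(models$wheeze, nWheezeLike, deriveSeed(recSeed, "w"))
  allDur <- c(dC, dW)
  lab <- c(rep("otherCrackle", nCrackleLike), rep("otherWheeze", nWheezeLike))
  if (!length(allDur)) {
    return(emptyEvents())
  }
  keep <- if (avoidOverlap && nrow(ars)) {
    cbind(ars$start, ars$end)
  }
  withSeed(deriveSeed(recSeed, "place"), {
    starts <- placeEvents(duration(rec), allDur, keep)
    out <- data.frame(
      start = starts, end = starts + allDur, label = lab,
      stringsAsFactors = FALSE
    )
    out[order(out$start), , drop = FALSE]
  })
}

#' Excerpt an annotated event from a recording
#'
#' Returns a waveform of exactly `round(maxLen * rate)` samples for events
#' up to `maxLen` seconds: the event is centered and symmetrically
#' zero-padded (the extra sample going to the right when the pad is odd).
#' Events longer than `maxLen` are truncated to their first `maxLen`
#' seconds and returned without padding. Event-to-sample conversion rounds
#' the start down and the end up, so no sample is dropped.
#'
#' @param rec an [AudioRecording-class].
#' @param event one-row data.frame (or list) with `start` and `end` in
#'   seconds.
#' @param policy an [excerptPolicy()].
#' @return numeric waveform.
#' @examples
#' rec <- AudioRecording(stats::rnorm(8000), 4000, "p", "r")
#' length(excerptEvent(rec, list(start = 0.5, end = 1.5)))
#' @export
excerptEvent <- function(rec, event, policy = excerptPolicy()) {
  s <- event$start
  e <- event$end
  if (s < 0 || e <= s || s >= duration(rec)) {
    stop("event outside recording bounds")
  }
  e <- min(e, duration(rec))
  nOut <- round(policy$maxLen * rate(rec))
  idx <- eventSampleRange(s, e, rate(rec))
  idx[2] <- min(idx[2], length(samples(rec)))
  wave <- samples(rec)[idx[1]:idx[2]]
  if (length(wave) >= nOut) {
    return(wave[seq_len(nOut)])
  }
  padTotal <- nOut - length(wave)
  padLeft <- padTotal %/% 2
  c(rep(0, padLeft), wave, rep(0, padTotal - padLeft))
}

#' Tabulate events per class
#'
#' Bookkeeping helper mirroring corpus summary tables: event counts per
#' label, optionally per split.
#'
#' @param events data.frame with a `label` column, or a list of them.
#' @return named integer vector of counts.
#' @export
countEventsByClass <- function(events) {
  if (is.data.frame(events)) events <- list(events)
  labs <- unlist(lapply(events, function(e) as.character(e$label)))
  table(factor(labs, levels = EVENT_LABELS))
}
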