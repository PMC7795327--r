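# Audio and annotation I/O, resampling, participant-based splitting.
# The same interfaces serve synthetic corpora and the ICBHI respiratory
# sound database layout (per-event text files mapped onto one canonical
# TSV dialect).

#' Read a 16-bit PCM RIFF/WAVE file
#'
#' Minimal reader for the only container this package uses: PCM, 16 bits
#' per sample. Stereo files are averaged to mono with a warning.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `rate` (Hz).
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL
  channels <- NULL
  bits <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      audioFormat <- fmt[1]
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little") # byte rate
      readBin(con, "integer", 1, 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (audioFormat != 1L || bits != 16L) {
        stop("only 16-bit PCM WAV is supported: ", path)
      }
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      n <- size %/% 2L
      data <- readBin(con, "integer", n, 2, endian = "little", signed = TRUE)
      if (size %% 2L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(data) && !is.null(rate)) break
  }
  if (is.null(rate) || is.null(data)) stop("corrupt WAV file: ", path)
  if (length(data) == 0L) stop("zero-length audio in ", path)
  if (channels > 1L) {
    warning("averaging ", channels, "-channel audio to mono: ", path)
    nf <- length(data) %/% channels
    data <- rowMeans(matrix(data[seq_len(nf * channels)],
      ncol = channels, byrow = TRUE
    ))
  }
  list(samples = data / 32768, rate = rate)
}

#' Write a 16-bit PCM mono WAV file
#'
#' @param samples numeric amplitudes; values outside \[-1, 1\] are clipped.
#' @param rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little") # PCM
  writeBin(1L, con, 2, endian = "little") # mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Resample a waveform with an anti-aliased polyphase filter
#'
#' Thin wrapper over [signal::resample()] working on integer-ratio rate
#' pairs. Applying it at the target rate is a no-op.
#'
#' @param samples numeric waveform.
#' @param from,to source and target rates in Hz.
#' @return resampled numeric waveform.
#' @export
resampleWave <- function(samples, from, to) {
  if (from == to) {
    return(samples)
  }
  f <- round(from)
  t <- round(to)
  g <- gcdInt(f, t)
  y <- signal::resample(samples, t %/% g, f %/% g)
  # keep duration within one sample period of the original
  nTarget <- round(length(samples) * to / from)
  if (length(y) > nTarget) y <- y[seq_len(nTarget)]
  if (length(y) < nTarget) y <- c(y, rep(0, nTarget - length(y)))
  as.numeric(y)
}

gcdInt <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Load a recording from disk at a target rate
#'
#' Reads a PCM WAV file, averages multi-channel audio to mono, and
#' resamples to `targetRate` (4000 Hz by default: the signal of interest
#' lies below 2000 Hz, so this keeps full Fourier resolution over the
#' band that matters while normalizing the mixed native rates).
#'
#' @param path WAV file path.
#' @param targetRate target sampling rate in Hz.
#' @param participantId,recordingId identifiers; defaulted from the
#'   file name (`<participant>_...` prefix convention).
#' @return an [AudioRecording-class].
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(sin(2 * pi * 440 * (0:8000) / 8000), 8000, f)
#' rec <- loadRecording(f, targetRate = 4000)
#' rate(rec)
#' @export
loadRecording <- function(path, targetRate = 4000,
                          participantId = NULL, recordingId = NULL) {
  if (!is.numeric(targetRate) || targetRate <= 0) {
    stop("targetRate must be positive")
  }
  w <- readWav(path)
  base <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  if (is.null(recordingId)) recordingId <- base
  if (is.null(participantId)) participantId <- strsplit(base, "_")[[1]][1]
  AudioRecording(
    resampleWave(w$samples, w$rate, targetRate), targetRate,
    participantId, recordingId
  )
}

#' Read an event annotation TSV
#'
#' Canonical dialect: UTF-8, header `start	end	label`, times in seconds.
#' Events are returned sorted by start time and labels validated against
#' the crackle/wheeze/other vocabulary.
#'
#' @param path TSV file path.
#' @return data.frame with columns start, end, label.
#' @export
readEvents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !identical(lines[1], "start\tend\tlabel")) {
    stop("missing 'start\tend\tlabel' header in ", path)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(emptyEvents())
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    lineNo <- i + 1L
    if (length(p) != 3L) {
      stop(sprintf("malformed row at line %d of %s", lineNo, path))
    }
    s <- suppressWarnings(as.numeric(p[1]))
    e <- suppressWarnings(as.numeric(p[2]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("non-numeric time at line %d of %s", lineNo, path))
    }
    if (s < 0 || e <= s) {
      stop(sprintf(
        "invalid interval [%s, %s) at line %d of %s", p[1], p[2], lineNo, path
      ))
    }
    if (!p[3] %in% EVENT_LABELS) {
      stop(sprintf("unknown label '%s' at line %d of %s", p[3], lineNo, path))
    }
  }
  ev <- data.frame(
    start = vapply(parts, function(p) as.numeric(p[1]), 0),
    end = vapply(parts, function(p) as.numeric(p[2]), 0),
    label = vapply(parts, function(p) p[3], ""),
    stringsAsFactors = FALSE
  )
  ev[order(ev$start, ev$end), , drop = FALSE]
}

#' Write an event annotation TSV
#'
#' Inverse of [readEvents()]: writes the canonical dialect with times to
#' three decimals minimum (sub-millisecond precision kept when present),
#' sorted by start so read-write round-trips are byte identical.
#'
#' @param events data.frame with columns start, end, label.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path) {
  checkEvents(events)
  events <- events[order(events$start, events$end), , drop = FALSE]
  fmt <- function(x) {
    s <- sprintf("%.6f", x)
    s <- sub("0+$", "", s)
    # keep at least three decimals
    dec <- nchar(sub(".*\\.", "", s))
    ifelse(dec < 3, sprintf("%.3f", x), s)
  }
  lines <- c(
    "start\tend\tlabel",
    if (nrow(events)) {
      paste(fmt(events$start), fmt(events$end), events$label, sep = "\t")
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Import respiratory-sound-database annotation text onto the canonical dialect
#'
#' Public lung-sound corpora such as the ICBHI respiratory sound
#' database ship whitespace-separated annotation text rather than this
#' package's TSV dialect. Two layouts are mapped: per-event rows
#' `start end label` (label containing "crackle" or "wheeze", case
#' insensitive) and per-cycle rows `start end crackleFlag wheezeFlag`
#' (one event per set flag, the flagged cycle interval becoming the
#' event interval). Rows flagging neither class are dropped.
#'
#' @param path annotation text file.
#' @return data.frame with columns start, end, label, sorted by start.
#' @export
importRsdEvents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- emptyEvents()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "[\t ]+")[[1]]
    if (length(p) < 3L) {
      stop(sprintf("malformed row at line %d of %s", i, path))
    }
    s <- suppressWarnings(as.numeric(p[1]))
    e <- suppressWarnings(as.numeric(p[2]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop(sprintf("invalid interval at line %d of %s", i, path))
    }
    if (length(p) >= 4L && !is.na(suppressWarnings(as.numeric(p[3])))) {
      # per-cycle flags: crackles then wheezes
      if (as.numeric(p[3]) > 0) {
        out <- rbind(out, data.frame(
          start = s, end = e, label = "crackle",
          stringsAsFactors = FALSE
        ))
      }
      if (as.numeric(p[4]) > 0) {
        out <- rbind(out, data.frame(
          start = s, end = e, label = "wheeze",
          stringsAsFactors = FALSE
        ))
      }
    } else {
      lab <- tolower(p[3])
      lab <- if (grepl("crackle", lab)) {
        "crackle"
      } else if (grepl("wheeze", lab)) {
        "wheeze"
      } else {
        stop(sprintf("unknown event label '%s' at line %d of %s",
          p[3], i, path))
      }
      out <- rbind(out, data.frame(
        start = s, end = e, label = lab, stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  checkEvents(out)
  out
}

#' Write a corpus manifest as YAML
#'
#' @param manifest a [DatasetManifest-class] whose recording entries carry
#'   `wav` and `events` file paths (as written by [writeCorpus()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  entries <- lapply(names(manifestRecordings(manifest)), function(id) {
    e <- manifestRecordings(manifest)[[id]]
    list(
      recording_id = id,
      participant_id = unname(manifestParticipants(manifest)[[id]]),
      wav = e$wav,
      events = e$eventsFile,
      split = if (id %in% names(manifestSplit(manifest))) {
        unname(manifestSplit(manifest)[[id]])
      }
    )
  })
  yaml::write_yaml(list(recordings = entries), path)
  invisible(path)
}

#' Read a corpus manifest from YAML
#'
#' Recording entries keep file paths (resolved relative to the manifest
#' location); audio is loaded lazily through [loadRecording()].
#'
#' @param path manifest YAML path.
#' @param loadAudio if `TRUE`, read WAV and event files eagerly.
#' @param targetRate rate passed to [loadRecording()].
#' @return a [DatasetManifest-class].
#' @export
readManifest <- function(path, loadAudio = TRUE, targetRate = 4000) {
  doc <- yaml::read_yaml(path)
  dir <- dirname(path)
  recs <- list()
  split <- character()
  part <- character()
  for (e in doc$recordings) {
    id <- e$recording_id
    wav <- file.path(dir, e$wav)
    evf <- file.path(dir, e$events)
    entry <- list(wav = e$wav, eventsFile = e$events)
    if (loadAudio) {
      entry$recording <- loadRecording(wav, targetRate,
        participantId = e$participant_id, recordingId = id
      )
      entry$events <- readEvents(evf)
    }
    recs[[id]] <- entry
    part[[id]] <- e$participant_id
    if (!is.null(e$split)) split[[id]] <- e$split
  }
  DatasetManifest(recs, split, part)
}

#' Split a manifest by participant
#'
#' Assigns every recording to the side its participant is assigned to,
#' guaranteeing participant disjointness by construction (the key
#' experimental-design constraint: material from one subject must never
#' appear on both sides).
#'
#' @param manifest a [DatasetManifest-class].
#' @param assignment named character vector, participantId -> "train"/"test".
#' @return list with `train` and `test` [DatasetManifest-class] objects.
#' @export
splitByParticipant <- function(manifest, assignment) {
  part <- manifestParticipants(manifest)
  missing <- setdiff(unique(part), names(assignment))
  if (length(missing)) {
    stop("unassigned participant(s): ", paste(missing, collapse = ", "))
  }
  if (!all(assignment %in% c("train", "test"))) {
    stop("assignment values must be 'train' or 'test'")
  }
  side <- assignment[part]
  names(side) <- names(part)
  pick <- function(s) {
    ids <- names(part)[side == s]
    DatasetManifest(
      manifestRecordings(manifest)[ids],
      structure(rep(s, length(ids)), names = ids),
      part[ids]
    )
  }
  out <- list(train = pick("train"), test = pick("test"))
  stopifnot(length(intersect(
    unique(manifestParticipants(out$train)),
    unique(manifestParticipants(out$test))
  )) == 0L)
  out
}
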