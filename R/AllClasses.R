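#' @import methods
NULL

#' Audio recording container
#'
#' Holds a single-channel sampled waveform together with its sampling rate
#' and the participant / recording identifiers used for patient-based
#' splitting. Amplitudes are dimensionless reals (PCM samples scaled to
#' \[-1, 1\] when read from disk).
#'
#' @slot samples numeric vector of amplitudes.
#' @slot rate sampling rate in Hz.
#' @slot participantId participant identifier (splitting unit).
#' @slot recordingId recording identifier, unique within a manifest.
#'
#' @seealso [AudioRecording()], [loadRecording()]
#' @exportClass AudioRecording
setClass("AudioRecording",
  representation(
    samples = "numeric",
    rate = "numeric",
    participantId = "character",
    recordingId = "character"
  )
)

setValidity("AudioRecording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive finite number")
  if (length(object@samples) == 0L)
    msg <- c(msg, "samples must be non-empty")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@participantId) != 1L || length(object@recordingId) != 1L)
    msg <- c(msg, "participantId and recordingId must be single strings")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioRecording
#'
#' @param samples numeric amplitude vector.
#' @param rate sampling rate in Hz.
#' @param participantId,recordingId identifiers.
#' @return an [AudioRecording-class] object.
#' @examples
#' rec <- AudioRecording(sin(2 * pi * 100 * (0:3999) / 4000), 4000, "p1", "p1_r1")
#' duration(rec)
#' @export
AudioRecording <- function(samples, rate, participantId = "unknown",
                           recordingId = "unknown") {
  new("AudioRecording",
    samples = as.numeric(samples), rate = as.numeric(rate),
    participantId = as.character(participantId),
    recordingId = as.character(recordingId)
  )
}

#' @describeIn AudioRecording-class waveform samples
#' @param x an `AudioRecording`.
#' @export
samples <- function(x) x@samples

#' @describeIn AudioRecording-class sampling rate in Hz
#' @export
rate <- function(x) x@rate

#' @describeIn AudioRecording-class participant identifier
#' @export
participantId <- function(x) x@participantId

#' @describeIn AudioRecording-class recording identifier
#' @export
recordingId <- function(x) x@recordingId

#' @describeIn AudioRecording-class duration in seconds
#' @export
duration <- function(x) length(x@samples) / x@rate

setMethod("show", "AudioRecording", function(object) {
  cat(sprintf(
    "AudioRecording '%s' (participant '%s'): %.3f s at %g Hz\n",
    object@recordingId, object@participantId,
    length(object@samples) / object@rate, object@rate
  ))
})

#' Time-frequency image
#'
#' A normalized magnitude time-frequency image, either on a linear
#' frequency axis (spectrogram) or a mel-filterbank axis (mel spectrogram).
#' Values are stored as a frequency-by-time matrix; `freqs` gives bin
#' center frequencies in Hz (or mel-band centers for mel scale) and
#' `times` the frame center times in seconds.
#'
#' @slot values numeric matrix, rows = frequency (or mel band), cols = time.
#' @slot freqs numeric vector of row center frequencies (Hz).
#' @slot times numeric vector of frame center times (s).
#' @slot scale `"linear"` or `"mel"`.
#' @slot normalized logical; `TRUE` after min-max scaling to \[0, 1\].
#'
#' @seealso [stftSpectrogram()], [melSpectrogram()], [normalizeImage()]
#' @exportClass TFImage
setClass("TFImage",
  representation(
    values = "matrix",
    freqs = "numeric",
    times = "numeric",
    scale = "character",
    normalized = "logical"
  )
)

setValidity("TFImage", function(object) {
  msg <- character()
  if (!object@scale %in% c("linear", "mel"))
    msg <- c(msg, "scale must be 'linear' or 'mel'")
  if (nrow(object@values) != length(object@freqs))
    msg <- c(msg, "freqs length must equal row count")
  if (ncol(object@values) != length(object@times))
    msg <- c(msg, "times length must equal column count")
  if (anyNA(object@values))
    msg <- c(msg, "values must not contain NA")
  if (isTRUE(object@normalized) && length(object@values) &&
      (min(object@values) < 0 || max(object@values) > 1))
    msg <- c(msg, "normalized image must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

TFImage <- function(values, freqs, times, scale, normalized = FALSE) {
  new("TFImage",
    values = values, freqs = as.numeric(freqs), times = as.numeric(times),
    scale = scale, normalized = normalized
  )
}

#' @describeIn TFImage-class magnitude matrix (frequency x time)
#' @param x a `TFImage`.
#' @export
tfValues <- function(x) x@values

#' @describeIn TFImage-class row center frequencies
#' @export
tfFreqs <- function(x) x@freqs

#' @describeIn TFImage-class frame center times
#' @export
tfTimes <- function(x) x@times

#' @describeIn TFImage-class frequency scale ("linear" or "mel")
#' @export
tfScale <- function(x) x@scale

setMethod("show", "TFImage", function(object) {
  cat(sprintf(
    "TFImage (%s scale): %d x %d (frequency x time)%s\n",
    object@scale, nrow(object@values), ncol(object@values),
    if (object@normalized) ", normalized [0,1]" else ""
  ))
})

setMethod("dim", "TFImage", function(x) dim(x@values))

#' Dataset manifest
#'
#' Binds recordings (or references to recording files), their annotated
#' event tables and a train/test split assignment. The split invariant is
#' participant disjointness: no participant may contribute recordings to
#' both sides.
#'
#' @slot recordings named list; each element is a list with components
#'   `recording` (an [AudioRecording-class] or a file path) and `events`
#'   (a data.frame with columns start, end, label).
#' @slot split named character vector mapping recordingId to
#'   `"train"` or `"test"` (may be empty before assignment).
#' @slot participants named character vector mapping recordingId to
#'   participantId.
#'
#' @exportClass DatasetManifest
setClass("DatasetManifest",
  representation(
    recordings = "list",
    split = "character",
    participants = "character"
  )
)

setValidity("DatasetManifest", function(object) {
  msg <- character()
  ids <- names(object@recordings)
  if (length(ids) && anyDuplicated(ids))
    msg <- c(msg, "recording ids must be unique")
  if (length(object@split)) {
    if (!all(object@split %in% c("train", "test")))
      msg <- c(msg, "split values must be 'train' or 'test'")
    part <- object@participants[names(object@split)]
    tr <- unique(part[object@split == "train"])
    te <- unique(part[object@split == "test"])
    if (length(intersect(tr, te)))
      msg <- c(msg, "a participant appears in both train and test")
  }
  if (length(msg)) msg else TRUE
})

DatasetManifest <- function(recordings, split = character(), participants) {
  new("DatasetManifest",
    recordings = recordings, split = split,
    participants = participants
  )
}

#' @describeIn DatasetManifest-class list of recording entries
#' @param x a `DatasetManifest`.
#' @export
manifestRecordings <- function(x) x@recordings

#' @describeIn DatasetManifest-class split assignment (recordingId -> side)
#' @export
manifestSplit <- function(x) x@split

#' @describeIn DatasetManifest-class participant map (recordingId -> participant)
#' @export
manifestParticipants <- function(x) x@participants

setMethod("show", "DatasetManifest", function(object) {
  n <- length(object@recordings)
  np <- length(unique(object@participants))
  cat(sprintf(
    "DatasetManifest: %d recording(s), %d participant(s)%s\n", n, np,
    if (length(object@split)) {
      sprintf(
        " [train %d / test %d]",
        sum(object@split == "train"), sum(object@split == "test")
      )
    } else ""
  ))
})

setMethod("length", "DatasetManifest", function(x) length(x@recordings))
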