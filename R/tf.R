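# Time-frequency representations: STFT magnitude spectrogram and mel
# spectrogram. The frame convention (no edge padding, hop = window/4) is
# pinned down by the canonical image size: a 2 s excerpt at 4000 Hz with a
# 32 ms window and 75% overlap yields exactly 247 frames x 257 bins.

#' STFT configuration
#'
#' @param windowKind `"hamming"`, `"blackman_harris"` or `"rectangular"`.
#' @param windowMs analysis window length in milliseconds.
#' @param nFft transform length in points; windows shorter than `nFft`
#'   are zero-padded on the right.
#' @param overlap fractional overlap between successive windows.
#' @return an object of class `STFTConfig`.
#' @export
stftConfig <- function(windowKind = "blackman_harris", windowMs = 32,
                       nFft = 512, overlap = 0.75) {
  windowKind <- match.arg(
    windowKind, c("hamming", "blackman_harris", "rectangular")
  )
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (windowMs <= 0 || nFft <= 0) stop("windowMs and nFft must be positive")
  structure(
    list(
      windowKind = windowKind, windowMs = windowMs,
      nFft = as.integer(nFft), overlap = overlap
    ),
    class = "STFTConfig"
  )
}

windowSamples <- function(cfg, rateHz) {
  w <- round(cfg$windowMs / 1000 * rateHz)
  if (w > cfg$nFft) {
    stop("window length in samples exceeds nFft")
  }
  as.integer(w)
}

hopSamples <- function(cfg, rateHz) {
  max(1L, as.integer(round(windowSamples(cfg, rateHz) * (1 - cfg$overlap))))
}

# Symmetric analysis windows.
makeWindow <- function(kind, n) {
  if (n == 1L) {
    return(1)
  }
  i <- seq_len(n) - 1L
  switch(kind,
    rectangular = rep(1, n),
    hamming = 0.54 - 0.46 * cos(2 * pi * i / (n - 1)),
    blackman_harris = {
      a <- c(0.35875, 0.48829, 0.14128, 0.01168)
      a[1] - a[2] * cos(2 * pi * i / (n - 1)) +
        a[3] * cos(4 * pi * i / (n - 1)) -
        a[4] * cos(6 * pi * i / (n - 1))
    },
    stop("unknown window kind: ", kind)
  )
}

#' Number of analysis frames
#'
#' `floor((L - W) / H) + 1` frames for a signal of `L` samples, window
#' `W`, hop `H`, without edge padding.
#'
#' @param nSamples signal length in samples.
#' @param window window length in samples.
#' @param hop hop in samples.
#' @return integer frame count.
#' @export
nFrames <- function(nSamples, window, hop) {
  if (nSamples < window) stop("window longer than signal")
  as.integer((nSamples - window) %/% hop + 1L)
}

# Signal -> window-length x frames matrix (columns are frames).
frameSignal <- function(wave, window, hop) {
  t <- nFrames(length(wave), window, hop)
  idx <- outer(seq_len(window), (seq_len(t) - 1L) * hop, "+")
  matrix(wave[idx], nrow = window)
}

#' Magnitude spectrogram via the short-time Fourier transform
#'
#' Frames the waveform (no edge padding), applies the analysis window,
#' zero-pads each frame to `nFft` points and returns one-sided magnitudes
#' (`nFft/2 + 1` bins).
#'
#' @param wave numeric waveform.
#' @param cfg an [stftConfig()].
#' @param rateHz sampling rate in Hz.
#' @return a linear-scale [TFImage-class] (not yet normalized).
#' @examples
#' img <- stftSpectrogram(stats::rnorm(8000), stftConfig(), 4000)
#' dim(img) # 257 x 247
#' @export
stftSpectrogram <- function(wave, cfg = stftConfig(), rateHz = 4000) {
  if (anyNA(wave) || any(!is.finite(wave))) stop("waveform must be finite")
  w <- windowSamples(cfg, rateHz)
  h <- hopSamples(cfg, rateHz)
  frames <- frameSignal(wave, w, h) * makeWindow(cfg$windowKind, w)
  if (w < cfg$nFft) {
    frames <- rbind(frames, matrix(0, cfg$nFft - w, ncol(frames)))
  }
  nBins <- cfg$nFft %/% 2L + 1L
  mag <- Mod(stats::mvfft(frames))[seq_len(nBins), , drop = FALSE]
  freqs <- (seq_len(nBins) - 1L) * rateHz / cfg$nFft
  times <- ((seq_len(ncol(mag)) - 1L) * h + w / 2) / rateHz
  TFImage(mag, freqs, times, "linear")
}

#' Hz to mel conversion
#'
#' `m = 2595 log10(1 + f / 700)`: strictly increasing, 0 at 0 Hz.
#'
#' @param f frequency in Hz (non-negative).
#' @return mel value(s).
#' @export
hzToMel <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  2595 * log10(1 + f / 700)
}

#' @rdname hzToMel
#' @param m mel value(s).
#' @export
melToHz <- function(m) {
  700 * (10^(m / 2595) - 1)
}

#' Triangular mel filterbank
#'
#' `nMels` triangular filters with centers uniformly spaced on the mel
#' scale from 0 Hz to `fMax`, evaluated at the linear bin frequencies.
#' Filters are area-unnormalized (peak 1).
#'
#' @param nMels number of bands.
#' @param binFreqs linear bin center frequencies in Hz.
#' @param fMax upper edge in Hz (Nyquist by default).
#' @return `nMels` x `length(binFreqs)` matrix.
#' @export
melFilterbank <- function(nMels, binFreqs, fMax = max(binFreqs)) {
  if (nMels > length(binFreqs)) {
    stop("nMels exceeds the number of frequency bins")
  }
  edges <- melToHz(seq(0, hzToMel(fMax), length.out = nMels + 2L))
  fb <- matrix(0, nMels, length(binFreqs))
  for (b in seq_len(nMels)) {
    lo <- edges[b]
    ce <- edges[b + 1L]
    hi <- edges[b + 2L]
    up <- (binFreqs - lo) / (ce - lo)
    down <- (hi - binFreqs) / (hi - ce)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel spectrogram from a linear spectrogram
#'
#' Applies a triangular mel filterbank ([melFilterbank()]) to a
#' linear-scale magnitude image.
#'
#' @param spec a linear-scale [TFImage-class].
#' @param nMels number of mel bands (64 canonical).
#' @return a mel-scale [TFImage-class]; `tfFreqs()` gives band center
#'   frequencies in Hz.
#' @export
melSpectrogram <- function(spec, nMels = 64) {
  if (tfScale(spec) != "linear") stop("input must be a linear spectrogram")
  fb <- melFilterbank(nMels, tfFreqs(spec))
  centers <- melToHz(
    seq(0, hzToMel(max(tfFreqs(spec))), length.out = nMels + 2L)
  )[seq_len(nMels) + 1L]
  TFImage(fb %*% tfValues(spec), centers, tfTimes(spec), "mel")
}

#' Min-max normalize a time-frequency image to \[0, 1\]
#'
#' Per-image affine scaling; a constant image maps to all zeros.
#' Idempotent on already-normalized images; the argmax location is
#' unchanged.
#'
#' @param img a [TFImage-class].
#' @return a normalized [TFImage-class].
#' @export
normalizeImage <- function(img) {
  v <- tfValues(img)
  if (anyNA(v) || any(!is.finite(v))) stop("image values must be finite")
  lo <- min(v)
  hi <- max(v)
  out <- if (hi > lo) (v - lo) / (hi - lo) else matrix(0, nrow(v), ncol(v))
  TFImage(out, tfFreqs(img), tfTimes(img), tfScale(img), normalized = TRUE)
}

#' Compute the canonical image pair for an event excerpt
#'
#' Convenience wrapper: STFT spectrogram and mel spectrogram, both
#' min-max normalized.
#'
#' @param wave event excerpt waveform.
#' @param cfg an [stftConfig()].
#' @param rateHz sampling rate in Hz.
#' @param nMels mel band count.
#' @return list with elements `spec` and `mel` ([TFImage-class]).
#' @export
eventImages <- function(wave, cfg = stftConfig(), rateHz = 4000, nMels = 64) {
  spec <- stftSpectrogram(wave, cfg, rateHz)
  list(
    spec = normalizeImage(spec),
    mel = normalizeImage(melSpectrogram(spec, nMels))
  )
}
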