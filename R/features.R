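# Multiscale acoustic feature extraction.
#
# 81 per-frame features (25 spectral + 26 MFCC + 30 melodic) computed on
# spectrograms at six window lengths (16..512 ms, 75% overlap), each
# summarized over frames by five statistics (mean, std, median, min, max):
# 81 x 5 x 6 = 2430 features per event. Channel names follow the
# `{stat}_{feature}_{windowMs}` scheme (e.g. std_melinharm250ms_32).

FEATURE_WINDOWS_MS <- c(16, 32, 64, 128, 256, 512)
FEATURE_STATS <- c("mean", "std", "median", "min", "max")

EPS <- 1e-12

spectralChannelNames <- function() {
  c(
    "speccentroid", "specspread", "specskewness", "speckurtosis",
    "speczcr", "specentropy", "specflatness", "specroughness",
    "specirregularity", "specflux", "specfluxinc", "specfluxhalfwave",
    "specfluxmedian", "specbright100", "specbright200", "specbright400",
    "specbright800", "specbright4ratio", "specbright8ratio",
    "specrolloff95", "specrolloff75", "specrolloff25", "specrolloff05",
    "specrolloffoutratio", "specrolloffiqratio"
  )
}

mfccChannelNames <- function() {
  c(paste0("mfcc", 1:13), paste0("deltamfcc", 1:13))
}

melodicChannelNames <- function() {
  base <- function(src) {
    unlist(lapply(c("pitch", "inharm", "voicing"), function(f) {
      paste0("mel", f, src, c("", "100ms", "250ms", "500ms", "1s"))
    }))
  }
  c(base(""), base("HF"))
}

#' Canonical per-frame channel names
#'
#' The fixed, ordered list of the 81 per-frame channels: 25 spectral,
#' 26 MFCC, 30 melodic.
#'
#' @return character vector of length 81.
#' @export
frameChannelNames <- function() {
  c(spectralChannelNames(), mfccChannelNames(), melodicChannelNames())
}

#' Canonical event feature names
#'
#' `{stat}_{feature}_{windowMs}` tokens for the requested window lengths;
#' 405 names per window, 2430 for the default six.
#'
#' @param windows window lengths in milliseconds.
#' @return character vector.
#' @export
featureVectorNames <- function(windows = FEATURE_WINDOWS_MS) {
  unlist(lapply(windows, function(w) {
    unlist(lapply(frameChannelNames(), function(f) {
      paste0(FEATURE_STATS, "_", f, "_", w)
    }))
  }))
}

# Guarded ratio: 0 when the denominator is (near) zero, so silent frames
# cannot poison event statistics.
safeDiv <- function(num, den) {
  ifelse(abs(den) < EPS, 0, num / den)
}

# Per-frame local spectral peaks above a relative threshold.
# Returns list(freq =, amp =) restricted to the strongest `maxPeaks`.
framePeaks <- function(mag, freqs, t, upMask, maxPeaks = 10L) {
  idx <- which(upMask[, t])
  if (!length(idx)) {
    return(NULL)
  }
  if (length(idx) > maxPeaks) {
    idx <- idx[order(mag[idx, t], decreasing = TRUE)[seq_len(maxPeaks)]]
    idx <- sort(idx)
  }
  list(freq = freqs[idx], amp = mag[idx, t])
}

# Sethares pairwise dissonance summed over spectral peaks.
setharesRoughness <- function(freq, amp) {
  n <- length(freq)
  if (n < 2L) {
    return(0)
  }
  tot <- 0
  for (j in seq_len(n - 1L)) {
    f1 <- freq[j]
    f2 <- freq[(j + 1L):n]
    s <- 0.24 / (0.0207 * f1 + 18.96)
    d <- exp(-3.5 * s * (f2 - f1)) - exp(-5.75 * s * (f2 - f1))
    tot <- tot + sum(amp[j] * amp[(j + 1L):n] * d)
  }
  tot
}

#' Spectral frame features
#'
#' The 25 spectral channels: spectral moments (magnitude-weighted
#' centroid, spread, skewness, excess kurtosis), zero-crossing rate
#' (crossings per second, on time-domain frames aligned with the
#' spectrogram), normalized Shannon entropy, flatness
#' (geometric/arithmetic mean), Sethares roughness over spectral peaks,
#' irregularity (squared successive peak amplitude differences over total
#' squared peak amplitude), four spectral-flux variants (Euclidean flux,
#' increase-only flux, halfwave-rectified flux, median-filtered flux;
#' first frame 0), energy proportion above 100/200/400/800 Hz plus the
#' 400/100 and 800/100 brightness ratios, energy rolloff at 95/75/25/5%
#' plus the 5/95 outlier and 25/75 interquartile rolloff ratios. All
#' ratios are defined as 0 when their denominator vanishes.
#'
#' @param spec a linear-scale [TFImage-class] (unnormalized magnitudes).
#' @param wave the waveform the spectrogram was computed from (for the
#'   zero-crossing rate); pass `NULL` to zero that channel.
#' @param cfg the [stftConfig()] used (framing for the ZCR).
#' @param rateHz sampling rate in Hz.
#' @return 25 x T matrix with [spectralChannelNames()] rownames.
#' @export
extractSpectralFeatures <- function(spec, wave = NULL, cfg = NULL,
                                    rateHz = 4000) {
  S <- tfValues(spec)
  if (!length(S)) stop("empty spectrogram")
  freqs <- tfFreqs(spec)
  t <- ncol(S)
  nb <- nrow(S)
  out <- matrix(0, 25L, t, dimnames = list(spectralChannelNames(), NULL))

  colSumS <- colSums(S)
  P <- sweep(S, 2L, pmax(colSumS, EPS), "/")
  P[, colSumS < EPS] <- 0
  centroid <- colSums(P * freqs)
  dev <- sweep(matrix(freqs, nb, t), 2L, centroid, "-")
  m2 <- colSums(P * dev^2)
  spread <- sqrt(m2)
  out["speccentroid", ] <- centroid
  out["specspread", ] <- spread
  out["specskewness", ] <- safeDiv(colSums(P * dev^3), spread^3)
  out["speckurtosis", ] <- safeDiv(colSums(P * dev^4), m2^2) -
    ifelse(m2 > EPS, 3, 0)

  if (!is.null(wave) && !is.null(cfg)) {
    w <- windowSamples(cfg, rateHz)
    h <- hopSamples(cfg, rateHz)
    fm <- frameSignal(wave, w, h)[, seq_len(t), drop = FALSE]
    sgn <- fm >= 0
    crossings <- colSums(sgn[-1L, , drop = FALSE] != sgn[-w, , drop = FALSE])
    out["speczcr", ] <- crossings / (w / rateHz)
  }

  logP <- ifelse(P > 0, log(P), 0)
  out["specentropy", ] <- -colSums(P * logP) / log(nb)
  out["specflatness", ] <- safeDiv(
    exp(colMeans(log(S + EPS))), colMeans(S) + EPS
  )

  # flux family: distance to the previous frame, first frame = 0
  if (t > 1L) {
    D <- S[, -1L, drop = FALSE] - S[, -t, drop = FALSE]
    flux <- sqrt(colSums(D^2))
    pos <- pmax(D, 0)
    out["specflux", ] <- c(0, flux)
    out["specfluxinc", ] <- c(0, sqrt(colSums(pos^2)))
    out["specfluxhalfwave", ] <- c(0, colSums(pos))
    out["specfluxmedian", ] <- stats::runmed(
      out["specflux", ],
      k = min(5L, t - (1 - t %% 2)), endrule = "median"
    )
  }

  E <- S^2
  totE <- pmax(colSums(E), EPS)
  bright <- function(fc) colSums(E[freqs >= fc, , drop = FALSE]) / totE
  b100 <- bright(100)
  b400 <- bright(400)
  b800 <- bright(800)
  out["specbright100", ] <- b100
  out["specbright200", ] <- bright(200)
  out["specbright400", ] <- b400
  out["specbright800", ] <- b800
  out["specbright4ratio", ] <- safeDiv(b400, b100)
  out["specbright8ratio", ] <- safeDiv(b800, b100)

  cumE <- apply(E, 2L, cumsum)
  roll <- function(p) {
    idx <- colSums(cumE < p * rep(totE, each = nb)) + 1L
    freqs[pmin(idx, nb)]
  }
  r95 <- roll(0.95)
  r75 <- roll(0.75)
  r25 <- roll(0.25)
  r05 <- roll(0.05)
  out["specrolloff95", ] <- r95
  out["specrolloff75", ] <- r75
  out["specrolloff25", ] <- r25
  out["specrolloff05", ] <- r05
  out["specrolloffoutratio", ] <- safeDiv(r05, r95)
  out["specrolloffiqratio", ] <- safeDiv(r25, r75)

  # peak-based channels
  colMax <- apply(S, 2L, max)
  upMask <- rbind(FALSE, S[-1L, , drop = FALSE] > S[-nb, , drop = FALSE]) &
    rbind(S[-nb, , drop = FALSE] >= S[-1L, , drop = FALSE], FALSE) &
    sweep(S, 2L, pmax(colMax * 0.01, EPS), ">")
  for (i in seq_len(t)) {
    pk <- framePeaks(S, freqs, i, upMask)
    if (is.null(pk) || length(pk$amp) < 2L) next
    out["specroughness", i] <- setharesRoughness(pk$freq, pk$amp)
    out["specirregularity", i] <- safeDiv(
      sum(diff(pk$amp)^2), sum(pk$amp^2)
    )
  }
  out
}

#' MFCC frame features
#'
#' 13 mel-frequency cepstral coefficients (log mel-band energies followed
#' by an orthonormal DCT-II, coefficients 1..13, the DC term dropped)
#' plus their first-order temporal differences (first frame delta = 0).
#'
#' @param spec a linear-scale [TFImage-class].
#' @param nMelBands mel bands for the MFCC filterbank (26 classic).
#' @param nCoef number of cepstral coefficients.
#' @return 26 x T matrix with [mfccChannelNames()] rownames.
#' @export
extractMfccFeatures <- function(spec, nMelBands = 26, nCoef = 13) {
  S <- tfValues(spec)
  if (!length(S)) stop("empty spectrogram")
  fb <- melFilterbank(nMelBands, tfFreqs(spec))
  logE <- log(fb %*% S + EPS)
  dct <- dctMatrix(nMelBands)[1L + seq_len(nCoef), , drop = FALSE]
  cc <- dct %*% logE
  delta <- if (ncol(cc) > 1L) {
    cbind(0, cc[, -1L, drop = FALSE] - cc[, -ncol(cc), drop = FALSE])
  } else {
    matrix(0, nCoef, 1L)
  }
  out <- rbind(cc, delta)
  rownames(out) <- mfccChannelNames()
  out
}

# Orthonormal DCT-II matrix (rows k = 0..n-1).
dctMatrix <- function(n) {
  k <- 0:(n - 1L)
  m <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  m[1L, ] <- m[1L, ] / sqrt(2)
  m
}

#' Pitch, voicing and inharmonicity curves
#'
#' Frame-level fundamental-frequency estimation through the
#' autocorrelation of each frame (computed spectrally via
#' Wiener-Khinchin), with parabolic interpolation of the autocorrelation
#' peak. Candidate fundamentals range from `fMin` (60 Hz by default, the
#' lower crackle band edge, further limited to two periods per window) up
#' to 1600 Hz, the highest fundamental reported for wheezes. A frame is
#' voiced when its normalized autocorrelation peak exceeds
#' `voicedThreshold`; unvoiced frames carry pitch 0. Voicing is the
#' fraction of spectral energy captured by the harmonic comb of the
#' estimated fundamental; inharmonicity is the energy-weighted deviation
#' of spectral peaks from integer multiples of it, scaled to \[0, 1\].
#'
#' @param wave waveform at `rateHz`.
#' @param cfg an [stftConfig()].
#' @param rateHz sampling rate in Hz.
#' @param fMin,fMax pitch search range in Hz.
#' @param voicedThreshold normalized autocorrelation voicing threshold.
#' @return list with numeric per-frame vectors `pitch` (Hz, 0 when
#'   unvoiced), `voicing` (\[0, 1\]) and `inharmonicity` (\[0, 1\]).
#' @export
pitchCurve <- function(wave, cfg = stftConfig(), rateHz = 4000,
                       fMin = 60, fMax = 1600, voicedThreshold = 0.35) {
  w <- windowSamples(cfg, rateHz)
  h <- hopSamples(cfg, rateHz)
  lagMin <- max(2L, as.integer(ceiling(rateHz / fMax)))
  lagMax <- min(as.integer(floor(rateHz / fMin)), w %/% 2L)
  if (lagMax <= lagMin) {
    stop("window too short for the requested minimum pitch")
  }
  fm <- frameSignal(wave, w, h)
  fm <- sweep(fm, 2L, colMeans(fm), "-")
  t <- ncol(fm)
  nPad <- 2L^ceiling(log2(2L * w))
  padded <- rbind(fm, matrix(0, nPad - w, t))
  sp <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(sp * Conj(sp), inverse = TRUE)) / nPad
  r0 <- pmax(ac[1L, ], EPS)
  lags <- lagMin:lagMax
  R <- ac[lags + 1L, , drop = FALSE]
  # a periodic frame peaks at every multiple of its period: take the
  # smallest local-maximum lag whose height is close to the global one,
  # then sharpen it by parabolic interpolation
  nr <- nrow(R)
  # interior local maxima only: the boundary at lagMin can sit on the
  # flank of the zero-lag main lobe and must not count as a candidate
  isPk <- rbind(FALSE,
    R[-c(1L, nr), , drop = FALSE] > R[-c(nr - 1L, nr), , drop = FALSE] &
      R[-c(1L, nr), , drop = FALSE] >= R[-c(1L, 2L), , drop = FALSE],
    FALSE
  )
  colMaxR <- apply(R, 2L, max)
  peak <- numeric(t)
  lagHat <- rep(NA_real_, t)
  for (i in seq_len(t)) {
    cand <- which(isPk[, i] & R[, i] >= 0.85 * colMaxR[i])
    if (!length(cand)) cand <- which.max(R[, i])
    l <- lags[cand[1L]]
    peak[i] <- ac[l + 1L, i] / r0[i]
    y0 <- ac[l, i]
    y1 <- ac[l + 1L, i]
    y2 <- if (l + 2L <= nPad) ac[l + 2L, i] else y1
    den <- y0 - 2 * y1 + y2
    delta <- if (abs(den) > EPS) 0.5 * (y0 - y2) / den else 0
    lagHat[i] <- l + max(-0.5, min(0.5, delta))
  }
  voiced <- peak > voicedThreshold & r0 > 1e-10
  pitch <- ifelse(voiced, rateHz / lagHat, 0)
  outOfRange <- pitch > fMax | pitch < rateHz / (lagMax + 0.5)
  pitch[outOfRange] <- 0

  # spectral support for comb voicing and inharmonicity
  nBins <- nPad %/% 2L + 1L
  mag <- Mod(sp[seq_len(nBins), , drop = FALSE])
  freqs <- (seq_len(nBins) - 1L) * rateHz / nPad

  # refine the coarse lag-domain estimate with the spectrum: the sampled
  # autocorrelation peak may sit on a period multiple (a submultiple of
  # the true fundamental) and is quantized to whole samples, so take the
  # strongest spectral peak at or above the candidate and sharpen it by
  # quadratic interpolation
  binHz0 <- rateHz / nPad
  for (i in seq_len(t)) {
    f0 <- pitch[i]
    if (f0 <= 0) next
    lo <- max(2L, floor(0.9 * f0 / binHz0) + 1L)
    hi <- min(nBins - 1L, ceiling(fMax / binHz0) + 1L)
    if (hi <= lo) next
    j <- lo + which.max(mag[lo:hi, i]) - 1L
    y0 <- mag[j - 1L, i]
    y1 <- mag[j, i]
    y2 <- mag[j + 1L, i]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) > EPS) 0.5 * (y0 - y2) / den else 0
    fHat <- (j - 1L + max(-0.5, min(0.5, off))) * binHz0
    if (fHat >= rateHz / (lagMax + 0.5) && fHat <= fMax) pitch[i] <- fHat
  }
  E <- mag^2
  totE <- colSums(E)
  colMax <- apply(mag, 2L, max)
  nb <- nBins
  upMask <- rbind(FALSE, mag[-1L, , drop = FALSE] > mag[-nb, , drop = FALSE]) &
    rbind(mag[-nb, , drop = FALSE] >= mag[-1L, , drop = FALSE], FALSE) &
    sweep(mag, 2L, pmax(colMax * 0.01, EPS), ">")
  voicing <- numeric(t)
  inharm <- numeric(t)
  binHz <- rateHz / nPad
  for (i in seq_len(t)) {
    f0 <- pitch[i]
    if (f0 <= 0 || totE[i] < EPS) next
    harmonics <- seq(f0, rateHz / 2 - binHz, by = f0)
    combIdx <- unique(unlist(lapply(harmonics, function(fh) {
      ctr <- round(fh / binHz) + 1L
      seq(max(1L, ctr - 1L), min(nb, ctr + 1L))
    })))
    voicing[i] <- min(1, sum(E[combIdx, i]) / totE[i])
    pk <- framePeaks(mag, freqs, i, upMask)
    if (!is.null(pk) && length(pk$amp)) {
      devi <- vapply(pk$freq, function(fp) {
        m <- max(1, round(fp / f0))
        min(abs(fp - m * f0), f0 / 2) / (f0 / 2)
      }, 0)
      inharm[i] <- sum(pk$amp * devi) / sum(pk$amp)
    }
  }
  list(pitch = pitch, voicing = voicing, inharmonicity = inharm)
}

#' Centered moving average
#'
#' Smooths a per-frame curve with a centered window, renormalizing at the
#' edges (partial windows average over the available frames).
#'
#' @param x numeric vector.
#' @param width window width in frames (>= 1).
#' @return smoothed numeric vector of the same length.
#' @export
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) <= 1L) {
    return(x)
  }
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Melodic frame features
#'
#' 30 channels: pitch, inharmonicity and voicing curves, raw and smoothed
#' with centered moving averages of 100, 250, 500 and 1000 ms (15
#' channels), computed on the raw waveform and again on its 400 Hz
#' high-pass filtered version (the high-pass removes ordinary breath
#' sounds, whose energy is negligible above 400 Hz).
#'
#' @param wave waveform at `rateHz`.
#' @param cfg an [stftConfig()].
#' @param rateHz sampling rate in Hz.
#' @param waveHF optional precomputed high-passed waveform.
#' @return 30 x T matrix with [melodicChannelNames()] rownames.
#' @export
extractMelodicFeatures <- function(wave, cfg = stftConfig(), rateHz = 4000,
                                   waveHF = NULL) {
  if (is.null(waveHF)) waveHF <- highpass400(wave, rateHz)
  h <- hopSamples(cfg, rateHz)
  frameDt <- h / rateHz
  widths <- pmax(1L, as.integer(round(c(0.1, 0.25, 0.5, 1) / frameDt)))
  block <- function(wv) {
    pc <- pitchCurve(wv, cfg, rateHz)
    rows <- lapply(
      list(pc$pitch, pc$inharmonicity, pc$voicing),
      function(curve) {
        rbind(
          curve,
          t(vapply(widths, function(wd) movingAverage(curve, wd),
            numeric(length(curve))
          ))
        )
      }
    )
    do.call(rbind, rows)
  }
  out <- rbind(block(wave), block(waveHF))
  rownames(out) <- melodicChannelNames()
  out
}

# 4th-order Butterworth high-pass at 400 Hz, zero-phase.
highpass400 <- function(wave, rateHz) {
  bf <- signal::butter(4, 400 / (rateHz / 2), type = "high")
  as.numeric(signal::filtfilt(bf, wave))
}

#' Summarize frame features into event statistics
#'
#' Five statistics per channel over the frame axis: mean, sample standard
#' deviation, median, minimum, maximum. Frame-order invariant; a single
#' frame yields std 0.
#'
#' @param block channels x T numeric matrix with rownames.
#' @return named numeric vector of length `5 * nrow(block)`.
#' @export
summarizeStatistics <- function(block) {
  if (is.null(dim(block)) || ncol(block) < 1L) stop("empty feature block")
  t <- ncol(block)
  stats5 <- function(x) {
    c(
      mean(x), if (t > 1L) stats::sd(x) else 0,
      stats::median(x), min(x), max(x)
    )
  }
  vals <- apply(block, 1L, stats5)
  out <- as.numeric(vals)
  names(out) <- as.vector(vapply(
    rownames(block), function(f) paste0(FEATURE_STATS, "_", f),
    character(5L)
  ))
  out
}

#' Extract the full multiscale event feature vector
#'
#' For each window length: an unnormalized magnitude spectrogram (Hamming
#' window by default, 75% overlap, transform length = next power of two
#' of the window), the 81 per-frame channels and their 5 summary
#' statistics. Concatenating over the six canonical windows gives the
#' 2430-dimensional event descriptor with [featureVectorNames()] names.
#'
#' @param wave event excerpt waveform (canonically 2 s at 4000 Hz).
#' @param rateHz sampling rate in Hz.
#' @param windows window lengths in milliseconds.
#' @param windowKind analysis window (Hamming canonical for features).
#' @param overlap fractional overlap.
#' @return named numeric vector of length `405 * length(windows)`.
#' @examples
#' v <- extractFeatureVector(stats::rnorm(8000), windows = c(32))
#' length(v) # 405
#' @export
extractFeatureVector <- function(wave, rateHz = 4000,
                                 windows = FEATURE_WINDOWS_MS,
                                 windowKind = "hamming", overlap = 0.75) {
  waveHF <- highpass400(wave, rateHz)
  out <- lapply(windows, function(wm) {
    wSamp <- round(wm / 1000 * rateHz)
    cfg <- stftConfig(
      windowKind = windowKind, windowMs = wm,
      nFft = 2L^ceiling(log2(wSamp)), overlap = overlap
    )
    spec <- stftSpectrogram(wave, cfg, rateHz)
    block <- rbind(
      extractSpectralFeatures(spec, wave, cfg, rateHz),
      extractMfccFeatures(spec),
      extractMelodicFeatures(wave, cfg, rateHz, waveHF)
    )
    v <- summarizeStatistics(block)
    names(v) <- paste0(names(v), "_", wm)
    v
  })
  unlist(out)
}
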