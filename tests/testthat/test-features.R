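# Multiscale feature extraction: channel counts, oracles, guards.

mkImage <- function(v, freqs) {
  arsound:::TFImage(v, freqs, seq_len(ncol(v)), "linear")
}

test_that("spectral moments collapse correctly on a point-mass spectrum", {
  freqs <- (0:256) * 4000 / 512
  v <- matrix(0, 257, 4)
  row500 <- which.min(abs(freqs - 500))
  v[row500, ] <- 3
  sf <- extractSpectralFeatures(mkImage(v, freqs))
  expect_equal(unname(sf["speccentroid", ]), rep(freqs[row500], 4))
  expect_equal(unname(sf["specspread", ]), rep(0, 4))
  expect_lt(max(sf["specflatness", ]), 1e-6)
  expect_equal(unname(sf["specentropy", ]), rep(0, 4), tolerance = 1e-12)
})

test_that("a flat spectrum has unit flatness and maximal entropy", {
  freqs <- (0:256) * 4000 / 512
  v <- matrix(1, 257, 3)
  sf <- extractSpectralFeatures(mkImage(v, freqs))
  expect_equal(unname(sf["specflatness", ]), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(sf["specentropy", ]), rep(1, 3), tolerance = 1e-12)
})

test_that("median-filtered flux suppresses a single spiked frame", {
  freqs <- (0:64) * 4000 / 128
  set.seed(4)
  base <- matrix(1 + 0.01 * stats::rnorm(65 * 9), 65, 9)
  spiked <- base
  spiked[, 5] <- 10
  sf <- extractSpectralFeatures(mkImage(spiked, freqs))
  # hand oracle: flux at t = Euclidean distance to the previous frame
  fluxOracle <- c(0, vapply(2:9, function(t) {
    sqrt(sum((spiked[, t] - spiked[, t - 1])^2))
  }, 0))
  expect_equal(unname(sf["specflux", ]), fluxOracle, tolerance = 1e-12)
  expect_equal(
    unname(sf["specfluxmedian", ]),
    as.numeric(stats::runmed(fluxOracle, 5, endrule = "median")),
    tolerance = 1e-12
  )
  # the spike is suppressed in the median channel
  expect_lt(max(sf["specfluxmedian", 5:6]), max(sf["specflux", 5:6]) / 2)
})

test_that("brightness and rolloff satisfy their order relations", {
  spec <- stftSpectrogram(canonicalExcerpt(), stftConfig(), 4000)
  sf <- extractSpectralFeatures(spec)
  expect_true(all(sf["specbright800", ] <= sf["specbright400", ] + 1e-12))
  expect_true(all(sf["specbright4ratio", ] >= 0 &
    sf["specbright4ratio", ] <= 1 + 1e-12))
  expect_true(all(sf["specrolloff05", ] <= sf["specrolloff95", ]))
  expect_true(all(sf["specrolloff25", ] <= sf["specrolloff75", ]))
})

test_that("MFCCs match an independent log-DCT oracle", {
  spec <- stftSpectrogram(canonicalExcerpt(), stftConfig(), 4000)
  mf <- extractMfccFeatures(spec)
  expect_equal(nrow(mf), 26)
  # independent oracle: filterbank -> log -> explicit DCT-II matrix
  fb <- melFilterbank(26, tfFreqs(spec))
  logE <- log(fb %*% tfValues(spec) + 1e-12)
  n <- 26
  dct <- sapply(0:(n - 1), function(nn) {
    sqrt(2 / n) * cos(pi * (1:13) * (2 * nn + 1) / (2 * n))
  })
  oracle <- dct %*% logE
  expect_equal(unname(mf[1:13, ]), unname(oracle), tolerance = 1e-8)
  # deltas: first frame zero, then differences
  expect_equal(unname(mf[14:26, 1]), rep(0, 13))
  expect_equal(
    unname(mf[14:26, -1]),
    unname(mf[1:13, -1] - mf[1:13, -ncol(mf)]),
    tolerance = 1e-12
  )

  # constant spectrogram over time: deltas vanish (up to BLAS rounding)
  cs <- mkImage(matrix(rep(stats::runif(257), 5), 257, 5),
    (0:256) * 4000 / 512)
  expect_lt(max(abs(extractMfccFeatures(cs)[14:26, ])), 1e-12)
})

test_that("pitch tracking recovers synthetic fundamentals within 2%", {
  cfg <- stftConfig("hamming", 64, 256, 0.75)
  for (f0 in c(220, 440, 880)) {
    w <- synthWheeze(1.5, f0, 4000, seed = 6)
    pc <- pitchCurve(w, cfg, 4000)
    voiced <- pc$pitch[pc$pitch > 0]
    expect_gt(length(voiced), 10)
    expect_lt(abs(stats::median(voiced) - f0) / f0, 0.02)
  }
  # silence: unvoiced everywhere, voicing ~ 0
  pcS <- pitchCurve(rep(0, 4000), cfg, 4000)
  expect_true(all(pcS$pitch == 0))
  expect_true(all(pcS$voicing < 0.05))
  expect_error(
    pitchCurve(stats::rnorm(4000), stftConfig("hamming", 1, 512), 4000,
      fMin = 60),
    "window too short"
  )
})

test_that("inharmonic tone pairs score higher inharmonicity than tones", {
  cfg <- stftConfig("hamming", 64, 256, 0.75)
  t <- (0:5999) / 4000
  harmonic <- sin(2 * pi * 440 * t) + 0.5 * sin(2 * pi * 880 * t)
  pair <- sin(2 * pi * 440 * t) + sin(2 * pi * 527 * t)
  ih1 <- stats::median(pitchCurve(harmonic, cfg, 4000)$inharmonicity)
  ih2 <- stats::median(pitchCurve(pair, cfg, 4000)$inharmonicity)
  expect_lt(ih1, 0.1)
  expect_gt(ih2, ih1)
})

test_that("melodic block has 30 channels and correct smoothing", {
  w <- canonicalExcerpt()
  mel <- extractMelodicFeatures(w, stftConfig("hamming", 64, 256), 4000)
  expect_equal(nrow(mel), 30)
  expect_equal(rownames(mel), arsound:::melodicChannelNames())

  # smoothing a unit impulse with a w-frame average gives a 1/w plateau
  x <- rep(0, 101)
  x[51] <- 1
  sm <- movingAverage(x, 5)
  expect_equal(sm[49:53], rep(1 / 5, 5))
  expect_equal(sum(sm), 1) # mass preserved in the interior
  # constant curve: smoothing is the identity
  expect_equal(movingAverage(rep(3.3, 40), 7), rep(3.3, 40))
})

test_that("summary statistics are correct and frame-order invariant", {
  block <- rbind(const = rep(2.5, 4), ramp = c(1, 2, 3, 4))
  s <- summarizeStatistics(block)
  expect_equal(unname(s["mean_const"]), 2.5)
  expect_equal(unname(s["std_const"]), 0)
  expect_equal(unname(s[c("median_const", "min_const", "max_const")]),
    rep(2.5, 3))
  expect_equal(unname(s["mean_ramp"]), 2.5)
  expect_equal(unname(s["median_ramp"]), 2.5)
  expect_equal(unname(s["min_ramp"]), 1)
  expect_equal(unname(s["max_ramp"]), 4)
  expect_equal(unname(s["std_ramp"]), stats::sd(1:4))

  perm <- block[, c(3, 1, 4, 2)]
  expect_equal(summarizeStatistics(perm), s)
  expect_error(summarizeStatistics(block[, 0, drop = FALSE]), "empty")
})

test_that("the event descriptor has 2430 canonically named channels", {
  v <- extractFeatureVector(canonicalExcerpt())
  expect_length(v, 2430)
  expect_equal(names(v), featureVectorNames())
  expect_equal(sum(names(v) == "std_melinharm250ms_32"), 1)
  expect_true(all(is.finite(v)))
  # count laws
  expect_length(frameChannelNames(), 81)
  expect_length(extractFeatureVector(canonicalExcerpt(), windows = 32), 405)
})

test_that("no input produces NaN or Inf, including degenerate excerpts", {
  silent <- rep(0, 8000)
  impulse <- c(rep(0, 4000), 1, rep(0, 3999))
  clipped <- pmin(pmax(3 * canonicalExcerpt(), -0.2), 0.2)
  for (w in list(silent, impulse, clipped)) {
    v <- extractFeatureVector(w, windows = c(32, 256))
    expect_true(all(is.finite(v)))
  }
})

test_that("ratio-style channels are invariant to global amplitude scaling", {
  w <- canonicalExcerpt()
  v1 <- extractFeatureVector(w, windows = 32)
  v2 <- extractFeatureVector(3.7 * w, windows = 32)
  invChannels <- grep(
    "speccentroid|specspread|specflatness|specrolloff(95|75|25|05)_|bright4ratio|bright8ratio|specentropy",
    names(v1)
  )
  expect_gt(length(invChannels), 30)
  expect_equal(v1[invChannels], v2[invChannels], tolerance = 1e-6)
})
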