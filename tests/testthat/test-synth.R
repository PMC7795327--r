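# Synthetic corpus generator: waveform primitives, annotation fidelity,
# determinism, duration statistics.

test_that("crackles are short, band-limited, explosive transients", {
  w <- synthCrackle(0.015, 4000, seed = 1)
  expect_length(w, 60) # round(duration * rate)
  expect_identical(w, synthCrackle(0.015, 4000, seed = 1))
  expect_false(identical(w, synthCrackle(0.015, 4000, seed = 2)))
  expect_error(synthCrackle(0, 4000, 1), "positive")
  expect_error(synthCrackle(0.2, 4000, 1), "0.1")

  # >= 90% of spectral energy inside 60-2000 Hz over 100 seeded draws
  fracs <- vapply(1:100, function(s) {
    x <- synthCrackle(stats::runif(1, 0.005, 0.05), 4000, seed = s)
    pad <- c(x, rep(0, 4096 - length(x)))
    e <- Mod(stats::fft(pad))[1:2049]^2
    f <- (0:2048) * 4000 / 4096
    sum(e[f >= 60 & f <= 2000]) / sum(e)
  }, 0)
  expect_true(all(fracs >= 0.9))

  # explosive onset: peak amplitude within the first third
  peaks <- vapply(1:50, function(s) {
    x <- synthCrackle(0.02, 4000, seed = s)
    which.max(abs(x)) / length(x)
  }, 0)
  expect_true(all(peaks <= 1 / 3))
})

test_that("wheezes are harmonic with the requested fundamental", {
  expect_length(synthWheeze(0.2, 400, 4000, 1), 800)
  for (f0 in c(150, 400, 750)) {
    w <- synthWheeze(0.5, f0, 4000, seed = 5)
    spec <- Mod(stats::fft(w))[1:(length(w) %/% 2)]
    fHat <- (which.max(spec) - 1) / 0.5
    # within one FFT bin plus the vibrato depth
    expect_lt(abs(fHat - f0), 2 + 0.01 * f0)
  }
  # different seeds: different waveform, same dominant frequency
  w1 <- synthWheeze(0.5, 400, 4000, seed = 1)
  w2 <- synthWheeze(0.5, 400, 4000, seed = 2)
  expect_false(identical(w1, w2))
  a1 <- (which.max(Mod(stats::fft(w1))[1:1000]) - 1) / 0.5
  a2 <- (which.max(Mod(stats::fft(w2))[1:1000]) - 1) / 0.5
  expect_lt(abs(a1 - 400), 2 + 0.01 * 400)
  expect_lt(abs(a2 - 400), 2 + 0.01 * 400)
  expect_error(synthWheeze(0.05, 400, 4000, 1), "exceed")
  expect_error(synthWheeze(0.5, 60, 4000, 1), "100")
})

test_that("recordings without events are pure background", {
  sr <- synthRecording(
    synthConfig(recordingDuration = 5, crackleRate = 0, wheezeRate = 0,
      disturbanceRate = 0, seed = 3),
    "p", "r"
  )
  expect_equal(nrow(sr$events), 0)
  expect_equal(samples(sr$recording), sr$background)
})

test_that("corpus generation is deterministic and annotations are faithful", {
  cfg <- synthConfig(
    nParticipants = 3, recordingsPerParticipant = 2,
    recordingDuration = 10, crackleRate = 3, wheezeRate = 1, seed = 17
  )
  c1 <- synthCorpus(cfg)
  c2 <- synthCorpus(cfg)
  for (id in names(manifestRecordings(c1))) {
    expect_identical(
      samples(manifestRecordings(c1)[[id]]$recording),
      samples(manifestRecordings(c2)[[id]]$recording)
    )
    expect_identical(
      manifestRecordings(c1)[[id]]$events,
      manifestRecordings(c2)[[id]]$events
    )
  }

  # events lie inside the recording and do not overlap one another
  for (id in names(manifestRecordings(c1))) {
    ev <- manifestRecordings(c1)[[id]]$events
    if (nrow(ev) < 2) next
    expect_true(all(ev$start >= 0 & ev$end <= 10))
    ord <- order(ev$start)
    expect_true(all(ev$end[ord][-nrow(ev)] <= ev$start[ord][-1] + 1e-12))
  }
})

test_that("injected events sit at the configured energy ratio", {
  cfg <- synthConfig(
    recordingDuration = 12, crackleRate = 4, wheezeRate = 2,
    disturbanceRate = 0, snrDb = 5, seed = 23
  )
  sr <- synthRecording(cfg, "p", "r")
  expect_gt(nrow(sr$events), 0)
  wav <- samples(sr$recording)
  for (i in seq_len(nrow(sr$events))) {
    i0 <- floor(sr$events$start[i] * 4000) + 1
    i1 <- min(length(wav), i0 + round((sr$events$end[i] -
      sr$events$start[i]) * 4000) - 1)
    ev <- wav[i0:i1] - sr$background[i0:i1]
    ratio <- 10 * log10(mean(ev^2) / mean(sr$background[i0:i1]^2))
    expect_lt(abs(ratio - 5), 1)
  }
})

test_that("injected wheeze durations fit the configured Burr model", {
  cfg <- synthConfig(
    nParticipants = 40, recordingsPerParticipant = 1,
    recordingDuration = 18, crackleRate = 0, wheezeRate = 8,
    disturbanceRate = 0, seed = 31
  )
  corpus <- synthCorpus(cfg)
  durs <- unlist(lapply(manifestRecordings(corpus), function(e) {
    e$events$end - e$events$start
  }))
  expect_gt(length(durs), 200)
  p <- burrOtherWheeze()
  ks <- suppressWarnings(
    stats::ks.test(durs, function(q) pburrTrunc(q, p))
  )
  expect_gt(ks$p.value, 0.01)
  expect_lt(
    max(abs(stats::ecdf(durs)(sort(durs)) -
      pburrTrunc(sort(durs), p))), 0.1
  )
})

test_that("a duration-blind energy-band rule separates crackles from wheezes", {
  # crackle energy is broadband/high, wheeze energy tonal/low: the band
  # ratio alone must beat chance, so classifiers have real signal beyond
  # event duration
  sr <- tinySplitCorpus()
  man <- c(
    manifestRecordings(sr$train), manifestRecordings(sr$test)
  )
  ratios <- c()
  labels <- c()
  for (e in man) {
    ev <- e$events
    for (i in seq_len(nrow(ev))) {
      w <- excerptEvent(e$recording, ev[i, ])
      sp <- Mod(stats::fft(w))[1:4000]^2
      f <- (0:3999) / 2
      keep <- f >= 100 & f <= 2000
      bandE <- tapply(sp[keep], floor(f[keep] / 100), sum)
      # share of energy in the strongest 100 Hz band: high for tonal
      # wheezes, low for broadband crackles
      ratios <- c(ratios, max(bandE) / sum(bandE))
      labels <- c(labels, ev$label[i])
    }
  }
  keep <- labels %in% c("crackle", "wheeze")
  expect_gt(sum(keep), 30)
  auc <- aucBinary(ratios[keep], labels[keep] == "wheeze")
  expect_gt(auc, 0.65)
})
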