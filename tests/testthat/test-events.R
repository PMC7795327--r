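# Negative-event generation and event excerpting.

test_that("fixed-mode negatives have exactly the requested duration atoms", {
  sr <- tinyRecording()
  rge <- generateFixedRge(
    sr$recording, sr$events, c("0.05" = 3, "0.15" = 2), seed = 4
  )
  expect_equal(nrow(rge), 5)
  expect_equal(sort(round(rge$end - rge$start, 9)),
    c(0.05, 0.05, 0.05, 0.15, 0.15))
  expect_setequal(unique(rge$label), c("other50", "other150"))
  expect_true(all(rge$start >= 0 & rge$end <= duration(sr$recording)))

  # per-file determinism from (seed, recordingId)
  expect_identical(
    rge, generateFixedRge(sr$recording, sr$events, c("0.05" = 3, "0.15" = 2),
      seed = 4)
  )

  # duration histogram has exactly two atoms
  many <- generateFixedRge(
    sr$recording, sr$events, c("0.05" = 10, "0.15" = 10), seed = 8
  )
  expect_setequal(round(many$end - many$start, 9), c(0.05, 0.15))
})

test_that("generated negatives do not overlap annotated events", {
  sr <- tinyRecording()
  for (seed in 1:20) {
    rge <- rbind(
      generateFixedRge(sr$recording, sr$events, c("0.05" = 3, "0.15" = 2),
        seed = seed),
      generateVariableRge(sr$recording, sr$events, 3, 2, seed = seed)
    )
    for (i in seq_len(nrow(rge))) {
      expect_true(all(
        rge$end[i] <= sr$events$start | rge$start[i] >= sr$events$end
      ))
    }
  }
})

test_that("variable-mode negatives follow the truncated Burr models", {
  sr <- tinyRecording()
  rge <- generateVariableRge(sr$recording, sr$events, 4, 2, seed = 21)
  dC <- with(rge, end - start)[rge$label == "otherCrackle"]
  dW <- with(rge, end - start)[rge$label == "otherWheeze"]
  expect_length(dC, 4)
  expect_length(dW, 2)
  expect_true(all(dC <= 0.1))
  expect_true(all(dW <= 2 & dW > 0.1))

  expect_equal(nrow(generateVariableRge(sr$recording, sr$events, 0, 0,
    seed = 1)), 0)

  # pooled otherWheeze durations pass a KS test against the truncated
  # distribution (CDF by quadrature) at alpha = 0.01
  pW <- burrOtherWheeze()
  mass <- stats::integrate(dburr, pW$lower, pW$upper, params = pW,
    rel.tol = 1e-10)$value
  cdf <- function(q) {
    vapply(q, function(qq) {
      stats::integrate(dburr, pW$lower, min(qq, pW$upper), params = pW,
        rel.tol = 1e-8)$value / mass
    }, 0)
  }
  pooled <- unlist(lapply(1:60, function(s) {
    r <- generateVariableRge(sr$recording, sr$events, 0, 5, seed = 1000 + s)
    r$end - r$start
  }))
  ks <- suppressWarnings(stats::ks.test(pooled, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("excerpting centers, pads, truncates and conserves energy", {
  set.seed(10)
  rec <- AudioRecording(stats::rnorm(6 * 4000), 4000, "p", "r")
  pol <- excerptPolicy(2)

  # 1.0 s event: 8000 samples with 2000 zeros each side
  w <- excerptEvent(rec, list(start = 2, end = 3), pol)
  expect_length(w, 8000)
  expect_true(all(w[1:2000] == 0))
  expect_true(all(w[6001:8000] == 0))
  expect_equal(w[2001:6000], samples(rec)[8001:12000])

  # energy conservation: zero padding adds nothing
  expect_equal(sum(w^2), sum(samples(rec)[8001:12000]^2))

  # 3.5 s event: only the first 2 s
  w2 <- excerptEvent(rec, list(start = 1, end = 4.5), pol)
  expect_length(w2, 8000)
  expect_equal(w2, samples(rec)[4001:12000])

  # exactly 2 s: unchanged
  w3 <- excerptEvent(rec, list(start = 0, end = 2), pol)
  expect_equal(w3, samples(rec)[1:8000])

  # odd pad: extra zero goes to the right
  w4 <- excerptEvent(rec, list(start = 0, end = 4000.5 / 4000), pol)
  # event covers ceil(4000.5) = 4001 samples; pad 3999 = 1999 + 2000
  expect_length(w4, 8000)
  expect_true(all(w4[1:1999] == 0))
  expect_equal(w4[2000:6000], samples(rec)[1:4001])
  expect_true(all(w4[6001:8000] == 0))

  expect_error(excerptEvent(rec, list(start = 7, end = 8), pol), "outside")
})

test_that("event bookkeeping counts classes per split", {
  sr <- tinyRecording()
  counts <- countEventsByClass(sr$events)
  expect_equal(sum(counts), nrow(sr$events))
  expect_named(counts)
})
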