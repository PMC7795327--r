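# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

# Small split corpus: 6 participants x 1 recording of 12 s.
tinySplitCorpus <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- synthConfig(
      nParticipants = 6, recordingsPerParticipant = 1,
      recordingDuration = 12, crackleRate = 4, wheezeRate = 2, seed = 42
    )
    corpus <- synthCorpus(cfg)
    .fixtures$tiny <- splitByParticipant(
      corpus, assignParticipants(corpus, 0.34, seed = 42)
    )
  }
  .fixtures$tiny
}

# One 12 s annotated recording.
tinyRecording <- function() {
  if (is.null(.fixtures$rec)) {
    .fixtures$rec <- synthRecording(
      synthConfig(recordingDuration = 12, crackleRate = 4, wheezeRate = 2,
        seed = 7),
      "p001", "p001_r01"
    )
  }
  .fixtures$rec
}

# A 2 s excerpt at 4000 Hz containing a wheeze over noise.
canonicalExcerpt <- function() {
  if (is.null(.fixtures$excerpt)) {
    set.seed(3)
    w <- synthWheeze(1.2, 350, 4000, seed = 3)
    wave <- 0.05 * stats::rnorm(8000)
    wave[2001:(2000 + length(w))] <- wave[2001:(2000 + length(w))] + w
    .fixtures$excerpt <- wave
  }
  .fixtures$excerpt
}

# Independent discrete mutual information (nats) via table().
miTable <- function(a, b) {
  tb <- table(a, b)
  p <- tb / sum(tb)
  pa <- rowSums(p)
  pb <- colSums(p)
  s <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
    }
  }
  s
}

# Independent brute-force greedy MIQ ranking over discrete columns.
bruteMiq <- function(x, y) {
  p <- ncol(x)
  rel <- vapply(seq_len(p), function(j) miTable(x[, j], y), 0)
  sel <- which.max(rel)
  while (length(sel) < p) {
    rest <- setdiff(seq_len(p), sel)
    crit <- vapply(rest, function(j) {
      red <- mean(vapply(sel, function(s) miTable(x[, j], x[, s]), 0))
      rel[j] / max(red, 1e-12)
    }, 0)
    sel <- c(sel, rest[which.max(crit)])
  }
  sel
}
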