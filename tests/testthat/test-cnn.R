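# Compact CNN: construction, gradients, training protocol.

tinyImageSet <- function(n = 40, h = 16, w = 16, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), length.out = n))
  arr <- array(stats::rnorm(n * h * w, sd = 0.1), dim = c(n, h, w, 1))
  for (i in seq_len(n)) {
    if (y[i] == "A") {
      arr[i, 4:8, 4:8, 1] <- arr[i, 4:8, 4:8, 1] + 1
    } else {
      arr[i, 10:14, 10:14, 1] <- arr[i, 10:14, 10:14, 1] + 1
    }
  }
  list(x = arr, y = y)
}

test_that("construction validates shapes and is seed-deterministic", {
  spec <- cnnSpec(list(c(247, 257), c(247, 64)), nClasses = 3)
  m1 <- buildCnn(spec, seed = 5)
  m2 <- buildCnn(spec, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_error(cnnSpec(list(c(4, 4)), filters = c(8, 8, 8)), "small")

  # outputs are a probability simplex before any training
  d <- tinyImageSet(6)
  small <- buildCnn(cnnSpec(list(c(16, 16)), filters = c(4), dense = 8,
    nClasses = 3), seed = 1)
  small$classes <- c("A", "B", "C")
  p <- predictCnn(small, list(d$x))
  expect_equal(unname(rowSums(p$probs)), rep(1, 6), tolerance = 1e-6)
  expect_error(predictCnn(small, list(d$x[, 1:8, , , drop = FALSE])), "shape")
})

test_that("analytic gradients match finite differences", {
  set.seed(8)
  spec <- cnnSpec(list(c(8, 8)), filters = c(2), dense = 4, nClasses = 2)
  model <- buildCnn(spec, seed = 2)
  xs <- list(array(stats::rnorm(3 * 8 * 8), dim = c(3, 8, 8, 1)))
  yOH <- diag(2)[c(1, 2, 1), ]
  fw <- arsound:::cnnForward(model, xs, training = TRUE)
  grads <- arsound:::cnnBackward(model, fw, xs, yOH)
  lossAt <- function(m) {
    arsound:::crossEntropy(arsound:::cnnForward(m, xs)$probs, yOH)
  }
  h <- 1e-6
  for (nm in c("K1_1", "kb1_1", "W1", "b1", "W2", "b2")) {
    idx <- sample(length(model$params[[nm]]), min(4, length(model$params[[nm]])))
    for (i in idx) {
      mp <- model
      mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- model
      mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      numg <- (lossAt(mp) - lossAt(mm)) / (2 * h)
      expect_equal(grads[[nm]][i], numg, tolerance = 1e-4)
    }
  }
})

test_that("the network can memorize a tiny balanced set", {
  d <- tinyImageSet(40)
  spec <- cnnSpec(list(c(16, 16)), filters = c(4, 8), dense = 16,
    nClasses = 2)
  m <- trainCnn(buildCnn(spec, 1), list(d$x), d$y,
    trainProtocol(epochs = 30, batch = 8, patience = 10, seed = 1))
  p <- predictCnn(m, list(d$x))
  expect_equal(mean(p$labels == d$y), 1)
  expect_lte(nrow(m$history), 30)
})

test_that("early stopping obeys the patience budget and restores the best", {
  d <- tinyImageSet(40, seed = 3)
  spec <- cnnSpec(list(c(16, 16)), filters = c(4), dense = 8, nClasses = 2)
  # a vanishing learning rate freezes the network: no epoch improves on
  # the first, so training must stop after exactly 1 + patience epochs
  frozen <- trainCnn(buildCnn(spec, 1), list(d$x), d$y,
    trainProtocol(epochs = 30, batch = 8, lr = 1e-30, patience = 4, seed = 1))
  expect_equal(nrow(frozen$history), 5)

  trained <- trainCnn(buildCnn(spec, 1), list(d$x), d$y,
    trainProtocol(epochs = 12, batch = 8, patience = 3, seed = 2))
  hist <- trained$history
  expect_lte(nrow(hist), 12)
  if (nrow(hist) < 12) {
    # stopped early: exactly `patience` epochs elapsed after the best
    expect_equal(nrow(hist) - which.min(hist$valLoss), 3)
  }
})

test_that("training and prediction are deterministic from the seed", {
  d <- tinyImageSet(30, seed = 5)
  spec <- cnnSpec(list(c(16, 16)), filters = c(4), dense = 8, nClasses = 2)
  proto <- trainProtocol(epochs = 4, batch = 8, patience = 2, seed = 9)
  m1 <- trainCnn(buildCnn(spec, 9), list(d$x), d$y, proto)
  m2 <- trainCnn(buildCnn(spec, 9), list(d$x), d$y, proto)
  expect_identical(m1$params, m2$params)
  # empty batch gives empty outputs
  p <- predictCnn(m1, list(d$x[0, , , , drop = FALSE]))
  expect_length(p$labels, 0)
  expect_equal(nrow(p$probs), 0)
})

test_that("dual-input models consume both image branches", {
  set.seed(11)
  n <- 24
  y <- factor(rep(c("A", "B", "C"), length.out = n))
  a1 <- array(stats::rnorm(n * 12 * 10), dim = c(n, 12, 10, 1))
  a2 <- array(stats::rnorm(n * 12 * 6), dim = c(n, 12, 6, 1))
  for (i in seq_len(n)) {
    a1[i, , , 1] <- a1[i, , , 1] + 0.8 * as.integer(y[i])
  }
  spec <- cnnSpec(list(c(12, 10), c(12, 6)), filters = c(3), dense = 8,
    nClasses = 3)
  m <- trainCnn(buildCnn(spec, 1), list(a1, a2), y,
    trainProtocol(epochs = 8, batch = 6, patience = 4, seed = 1))
  p <- predictCnn(m, list(a1, a2))
  expect_equal(unname(rowSums(p$probs)), rep(1, n), tolerance = 1e-6)
  expect_error(
    trainCnn(buildCnn(spec, 1), list(a1, a2), factor(rep("A", n)),
      trainProtocol(epochs = 4, batch = 6, patience = 2, seed = 1)),
    "two classes"
  )
})
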