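# Classical classifiers and the seeded hyperparameter search.

makeBlobs <- function(n = 60, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(stats::rnorm(n * 2), n),
    matrix(stats::rnorm(n * 2) + gap, n)
  )
  colnames(x) <- c("a", "b")
  list(x = x, y = factor(rep(c("A", "B"), each = n)))
}

test_that("search stays inside the declared ranges and is reproducible", {
  b <- makeBlobs()
  space <- defaultHyperparamSpace("svm_rbf")
  for (seed in 1:8) {
    m <- optimizeAndFit("svm_rbf", b$x, b$y, budget = 5, seed = seed)
    cfg <- attr(m, "chosenConfig")
    expect_gte(cfg$cost, space$cost$lower)
    expect_lte(cfg$cost, space$cost$upper)
    expect_gte(cfg$kernelScale, space$kernelScale$lower)
    expect_lte(cfg$kernelScale, space$kernelScale$upper)
  }
  m1 <- optimizeAndFit("svm_rbf", b$x, b$y, budget = 6, seed = 3)
  m2 <- optimizeAndFit("svm_rbf", b$x, b$y, budget = 6, seed = 3)
  expect_identical(attr(m1, "chosenConfig"), attr(m2, "chosenConfig"))
  expect_error(optimizeAndFit("svm_rbf", b$x, b$y, budget = 0), "budget")
})

test_that("tuned SVM-RBF separates well-separated blobs", {
  b <- makeBlobs(n = 80, gap = 5, seed = 2)
  m <- optimizeAndFit("svm_rbf", b$x, b$y, budget = 10, seed = 1)
  expect_gte(max(attr(m, "searchHistory")$validationAccuracy), 0.99)
  p <- predict(m, b$x)
  expect_gte(mean(p$labels == b$y), 0.99)
  expect_equal(unname(rowSums(p$probs)), rep(1, nrow(b$x)), tolerance = 1e-6)
})

test_that("regularized LDA matches the classical solution at tiny delta", {
  b <- makeBlobs(n = 100, gap = 3, seed = 4)
  own <- arsound:::fitLda(b$x, b$y, delta = 1e-9)
  ref <- MASS::lda(b$x, b$y)
  ours <- arsound:::predictLda(own, b$x)$labels
  theirs <- predict(ref, b$x)$class
  expect_gte(mean(as.character(ours) == as.character(theirs)), 0.99)
  # separable training data is classified perfectly
  m <- optimizeAndFit("lda", b$x, b$y, budget = 4, seed = 1)
  expect_gte(mean(predict(m, b$x)$labels == b$y), 0.99)
})

test_that("RUSBoost balances rounds and recovers the minority class", {
  set.seed(6)
  nMaj <- 190
  nMin <- 10
  x <- rbind(
    matrix(stats::rnorm(nMaj * 2), nMaj),
    matrix(stats::rnorm(nMin * 2) + 4, nMin)
  )
  colnames(x) <- c("a", "b")
  y <- factor(c(rep("maj", nMaj), rep("min", nMin)))
  m <- optimizeAndFit("rusboost", x, y, budget = 5, seed = 2)
  p <- predict(m, x)
  expect_gte(mean(p$labels[y == "min"] == "min"), 0.9)
  # per-round training subsets are class-balanced
  counts <- m$model$roundClassCounts
  expect_gt(length(counts), 0)
  for (tb in counts) expect_equal(length(unique(as.integer(tb))), 1L)
})

test_that("prediction validates channels and handles empty input", {
  b <- makeBlobs()
  m <- optimizeAndFit("lda", b$x, b$y, budget = 3, seed = 1)
  empty <- b$x[0, , drop = FALSE]
  p <- predict(m, empty)
  expect_length(p$labels, 0)
  bad <- b$x
  colnames(bad) <- c("a", "zz")
  expect_error(predict(m, bad), "channel")
})
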