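# Evaluation metrics: confusion collapse, formula oracles, AUC.

test_that("perfect predictions score 1 on every metric", {
  truth <- c("a", "a", "b", "b", "c")
  cm <- confusionMatrix(truth, truth)
  for (cl in c("a", "b", "c")) {
    m <- metricsFromConfusion(cm, cl)
    expect_equal(unname(m), rep(1, 5))
  }
  expect_equal(overallAccuracy(cm), 1)
})

test_that("hand-evaluated binary counts reproduce the formulas", {
  # TP = 4, FN = 1, FP = 2, TN = 3
  truth <- c(rep("pos", 5), rep("neg", 5))
  pred <- c(rep("pos", 4), "neg", "pos", "pos", rep("neg", 3))
  cm <- confusionMatrix(truth, pred, levels = c("pos", "neg"))
  expect_equal(unname(oneVsAll(cm, "pos")), c(4, 1, 2, 3))
  m <- metricsFromConfusion(cm, "pos")
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["f1"]), 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8))
  expect_equal(unname(m["mcc"]), (4 * 3 - 2 * 1) / sqrt(6 * 5 * 5 * 4))
})

test_that("degenerate all-one-class predictors get zero MCC", {
  truth <- c("pos", "pos", "neg", "neg")
  pred <- rep("pos", 4)
  cm <- confusionMatrix(truth, pred, levels = c("pos", "neg"))
  m <- metricsFromConfusion(cm, "pos")
  expect_equal(unname(m["mcc"]), 0)
  mNeg <- metricsFromConfusion(cm, "neg")
  expect_equal(unname(mNeg["precision"]), 0)
  expect_equal(unname(mNeg["f1"]), 0)
  expect_error(metricsFromConfusion(cm[0, 0, drop = FALSE], "pos"), "empty")
})

test_that("one-vs-all counts always sum to the total event count", {
  set.seed(12)
  for (trial in 1:10) {
    truth <- sample(c("a", "b", "c"), 50, TRUE)
    pred <- sample(c("a", "b", "c"), 50, TRUE)
    cm <- confusionMatrix(truth, pred)
    for (cl in c("a", "b", "c")) {
      expect_equal(sum(oneVsAll(cm, cl)), 50)
    }
    expect_equal(overallAccuracy(cm), sum(diag(as.matrix(cm))) / 50)
  }
})

test_that("AUC equals the Mann-Whitney statistic with tie credit", {
  # perfect separation
  expect_equal(aucBinary(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  # symmetry under score negation
  set.seed(13)
  s <- stats::rnorm(200)
  l <- stats::runif(200) < 0.4
  expect_equal(aucBinary(s, l), 1 - aucBinary(-s, l), tolerance = 1e-12)
  # agreement with wilcox.test's U statistic
  u <- stats::wilcox.test(s[l], s[!l])$statistic
  expect_equal(aucBinary(s, l), unname(u) / (sum(l) * sum(!l)),
    tolerance = 1e-12)
  # ties credited 0.5
  expect_equal(aucBinary(c(1, 1, 1, 1), c(T, T, F, F)), 0.5)
  # coin-flip labels give AUC near 0.5
  set.seed(14)
  n <- 10000
  sc <- stats::rnorm(n)
  lab <- sample(c(TRUE, FALSE), n, TRUE)
  expect_lt(abs(aucBinary(sc, lab) - 0.5), 0.02)
  expect_error(aucBinary(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})
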