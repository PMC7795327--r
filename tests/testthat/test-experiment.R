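# Experiment runner: event assembly, isolation, report structure.

test_that("swapping the negative mode leaves annotated events untouched", {
  spl <- tinySplitCorpus()
  evF <- assembleEvents(spl$train, "fixed", rgeSeed = 99)
  evV <- assembleEvents(spl$train, "variable", rgeSeed = 99)
  ars <- function(e) e[e$label %in% c("crackle", "wheeze"), 1:4]
  expect_identical(ars(evF), ars(evV))
  expect_setequal(
    unique(evF$label[!evF$label %in% c("crackle", "wheeze")]),
    c("other50", "other150")
  )
  expect_setequal(
    unique(evV$label[!evV$label %in% c("crackle", "wheeze")]),
    c("otherCrackle", "otherWheeze")
  )
  # negative generation is reproducible from the master seed
  expect_identical(evF, assembleEvents(spl$train, "fixed", rgeSeed = 99))
})

test_that("task definitions pick the matching negative class", {
  labs <- c("crackle", "wheeze", "other50", "other150", "otherCrackle",
    "otherWheeze")
  expect_equal(
    arsound:::taskClass(labs, "3class", "fixed"),
    c("crackle", "wheeze", "other", "other", NA, NA)
  )
  expect_equal(
    arsound:::taskClass(labs, "2class_crackles", "variable"),
    c("crackle", NA, NA, NA, "other", NA)
  )
  expect_equal(
    arsound:::taskClass(labs, "2class_wheezes", "fixed"),
    c(NA, "wheeze", NA, "other", NA, NA)
  )
})

test_that("a single-seed deterministic classifier reports zero spread", {
  spl <- tinySplitCorpus()
  cache <- new.env()
  rep1 <- runExperiment(
    experimentConfig("fixed", "fixed", "3class", "10MRMR", "lda", seeds = 0),
    spl$train, spl$test,
    windows = 32, budget = 2, cache = cache
  )
  expect_true(all(rep1$summary$sd == 0))
  expect_equal(nrow(rep1$perSeed), 1)

  # 3-class report carries F1/MCC columns for each class
  expect_true(all(
    c("accuracy", "f1_wheeze", "mcc_wheeze", "f1_crackle", "mcc_crackle",
      "f1_other", "mcc_other") %in% rep1$summary$metric
  ))
  expect_true(all(rep1$summary$mean >= -1 & rep1$summary$mean <= 1))
  cm <- rep1$confusions[["0"]]
  expect_equal(sum(cm), sum(rep1$eventCounts$test))
})

test_that("binary tasks add an AUC column and respect the positive class", {
  spl <- tinySplitCorpus()
  cache <- new.env()
  repC <- runExperiment(
    experimentConfig("variable", "variable", "2class_crackles", "10MRMR",
      "lda", seeds = 0),
    spl$train, spl$test,
    windows = 32, budget = 2, cache = cache
  )
  expect_true("auc" %in% repC$summary$metric)
  expect_equal(repC$classes, c("crackle", "other"))
  auc <- repC$summary$mean[repC$summary$metric == "auc"]
  expect_gte(auc, 0)
  expect_lte(auc, 1)
})

test_that("shared participants between manifests are rejected", {
  spl <- tinySplitCorpus()
  expect_error(
    runExperiment(
      experimentConfig("fixed", "fixed", "3class", "full", "lda", seeds = 0),
      spl$train, spl$train
    ),
    "share participants"
  )
})

test_that("the duration-only ablation uses nothing but event duration", {
  spl <- tinySplitCorpus()
  repD <- runExperiment(
    experimentConfig("fixed", "fixed", "3class", "full", "duration",
      seeds = 0),
    spl$train, spl$test
  )
  # fixed negatives make duration alone almost perfectly predictive
  expect_gt(reportAccuracy(repD), 0.85)
})
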