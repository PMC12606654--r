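test_that("confusion counting matches hand examples and rejects bad input", {
  expect_identical(confusionCounts(c(1, 0), c(0.9, 0.1)),
                   c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cts <- confusionCounts(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_identical(unname(cts[c("TP", "FP")]), c(0L, 0L))
  expect_error(confusionCounts(numeric(0), numeric(0)), "empty")
  expect_error(confusionCounts(c(1, 0), 0.5), "lengths")
})

test_that("confusion counts agree with a naive loop oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 1000
    labels <- rbinom(n, 1, 0.4)
    scores <- round(runif(n), 2)             # rounded: many threshold ties
    thr <- runif(1)
    expect_identical(confusionCounts(labels, scores, thr),
                     loop_confusion_oracle(labels, scores, thr))
  }
})

test_that("scalar metrics match the standard formulas", {
  m <- scalarMetrics(c(TP = 5, TN = 5, FP = 5, FN = 5))
  expect_equal(unname(m["mcc"]), 0)
  expect_equal(unname(m["acc"]), 0.5)
  perfect <- scalarMetrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1, 1))
  m2 <- scalarMetrics(c(TP = 8, TN = 6, FP = 2, FN = 4))
  expect_equal(unname(m2["acc"]), 0.7)
  expect_equal(unname(m2["sn"]), 2 / 3)
  expect_equal(unname(m2["sp"]), 0.75)
  expect_equal(unname(m2["precision"]), 0.8)
  expect_equal(unname(m2["f1"]), 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  expect_equal(unname(m2["mcc"]),
               (8 * 6 - 2 * 4) / sqrt(10 * 12 * 8 * 10))
})

test_that("zero denominators surface as NA, never silent zero", {
  m <- scalarMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m["sn"]))
  expect_true(is.na(m["precision"]))
  expect_true(is.na(m["f1"]))
  expect_true(is.na(m["mcc"]))
  expect_equal(unname(m["acc"]), 1)
})

test_that("scalar metrics agree with the formula oracle on random tables", {
  set.seed(202)
  for (rep in 1:1000) {
    cts <- setNames(as.numeric(rmultinom(1, sample(4:80, 1),
                                         runif(4, 0.05, 1))),
                    c("TP", "TN", "FP", "FN"))
    expect_equal(scalarMetrics(cts), loop_scalar_oracle(cts),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC equals the exhaustive pairwise oracle", {
  set.seed(303)
  labels <- rbinom(200, 1, 0.5)
  scores <- round(runif(200), 2)             # force ties
  expect_equal(rocAUC(labels, scores), pairwise_auc_oracle(labels, scores),
               tolerance = 1e-12)
  expect_equal(rocAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(rocAUC(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(rocAUC(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
  set.seed(404)
  labels <- rbinom(300, 1, 0.5)
  scores <- runif(300)
  a <- rocAUC(labels, scores)
  expect_equal(rocAUC(labels, plogis(7 * scores - 2)), a, tolerance = 1e-12)
  expect_equal(rocAUC(labels, rank(scores)), a, tolerance = 1e-12)
})

test_that("ROC and PR areas cross-check against pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(505)
  labels <- rbinom(250, 1, 0.45)
  scores <- runif(250)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(rocAUC(labels, scores), ref, tolerance = 1e-10)
})

test_that("PR AUC behaves correctly at the extremes", {
  expect_equal(prAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  set.seed(606)
  labels <- rbinom(2000, 1, 0.3)
  aucpr <- prAUC(labels, runif(2000))
  expect_lt(abs(aucpr - mean(labels)), 0.05)  # random scores -> prevalence
  expect_error(prAUC(c(0, 0), c(0.1, 0.2)), "both classes")
})

test_that("MCC flips sign when predicted labels are inverted", {
  set.seed(707)
  labels <- rbinom(200, 1, 0.5)
  scores <- runif(200)
  m1 <- scalarMetrics(confusionCounts(labels, scores, 0.5))
  m2 <- scalarMetrics(confusionCounts(labels, 1 - scores + 1e-9, 0.5))
  expect_equal(unname(m1["mcc"]), -unname(m2["mcc"]), tolerance = 1e-6)
})

test_that("evaluateScores assembles a full eight-metric report", {
  set.seed(808)
  labels <- rbinom(100, 1, 0.5)
  scores <- runif(100)
  rep <- evaluateScores(labels, scores, threshold = 0.5)
  m <- reportMetrics(rep)
  expect_named(m, c("acc", "sn", "sp", "precision", "f1", "mcc",
                    "auc", "aucpr"))
  expect_equal(sum(reportCounts(rep)), 100L)
  expect_equal(unname(m["auc"]), rocAUC(labels, scores))
})

test_that("curve points trace monotone ROC coordinates", {
  set.seed(909)
  labels <- rbinom(80, 1, 0.5)
  scores <- runif(80)
  roc <- curvePoints(labels, scores, "roc")
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  pr <- curvePoints(labels, scores, "pr")
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
})
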