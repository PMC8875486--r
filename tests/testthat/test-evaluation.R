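test_that("cross-validation folds partition the frames with the 4:1 inner split", {
  cv <- makeCvFolds(100, 5, seed = 3)
  expect_equal(sort(unlist(lapply(cv$folds, `[[`, "test"))), 1:100)
  for (f in cv$folds) {
    expect_equal(length(f$test), 20)
    expect_equal(length(f$train), 64)
    expect_equal(length(f$validation), 16)
    expect_length(intersect(f$test, c(f$train, f$validation)), 0)
    expect_length(intersect(f$train, f$validation), 0)
  }
  # property across random sizes
  set.seed(6)
  for (i in 1:10) {
    n <- sample(20:200, 1); k <- sample(2:6, 1)
    cv <- makeCvFolds(n, k, seed = i)
    sizes <- lengths(lapply(cv$folds, `[[`, "test"))
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sort(unlist(lapply(cv$folds, `[[`, "test"))), seq_len(n))
    for (f in cv$folds) {
      m <- length(f$train) + length(f$validation)
      expect_lt(abs(length(f$validation) - m / 5), 1)
      expect_equal(sort(c(f$test, f$train, f$validation)), seq_len(n))
    }
  }
  expect_error(makeCvFolds(4, 5), "cannot make")
})

test_that("metrics match hand-computed values from their definitions", {
  # TP=45 (ok,ok), FP=10, FN=5, TN=40 for the ok class
  yTrue <- c(rep("ok", 50), rep("no_ok", 50))
  yPred <- c(rep("ok", 45), rep("no_ok", 5), rep("ok", 10), rep("no_ok", 40))
  r <- computeMetrics(yTrue, yPred)
  expect_equal(r@acc, 0.85)
  expect_equal(r@precision, 45 / 55, tolerance = 1e-12)
  expect_equal(r@recall, 0.9)
  expect_equal(r@f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9), tolerance = 1e-12)
  expect_equal(sum(r@confusion), 100L)
  # perfect predictions
  p <- computeMetrics(yTrue, yTrue)
  expect_equal(p@acc, 1); expect_equal(p@f1, 1); expect_equal(p@kappa, 1)
  expect_identical(p@agreement, "Perfect")
  expect_error(computeMetrics(character(0), character(0)), "empty")
})

test_that("f1 is the harmonic mean of precision and recall in every report", {
  set.seed(14)
  for (i in 1:20) {
    yTrue <- sample(binaryLevels(), 60, replace = TRUE)
    yPred <- sample(binaryLevels(), 60, replace = TRUE)
    r <- computeMetrics(yTrue, yPred)
    expected <- if (r@precision + r@recall > 0)
      2 * r@precision * r@recall / (r@precision + r@recall) else 0
    expect_equal(r@f1, expected, tolerance = 1e-12)
    expect_equal(r@acc, sum(diag(r@confusion)) / sum(r@confusion))
  }
})

test_that("multi-class metrics are macro-averaged over the four groups", {
  set.seed(15)
  yTrue <- sample(1:4, 200, replace = TRUE)
  yPred <- ifelse(runif(200) < 0.7, yTrue, sample(1:4, 200, replace = TRUE))
  r <- computeMetrics(yTrue, yPred)
  m <- r@confusion
  prec <- vapply(1:4, function(i) if (sum(m[, i]) > 0) m[i, i] / sum(m[, i]) else 0,
                 numeric(1))
  rec <- vapply(1:4, function(i) if (sum(m[i, ]) > 0) m[i, i] / sum(m[i, ]) else 0,
                numeric(1))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  expect_equal(r@precision, mean(prec))
  expect_equal(r@recall, mean(rec))
  expect_equal(r@f1, mean(f1))
})

test_that("path evaluation kappa is consistent with its own confusion matrix", {
  set.seed(16)
  ref <- sample(binaryLevels(), 100, replace = TRUE)
  pred <- ifelse(runif(100) < 0.85, ref, sample(binaryLevels(), 100, TRUE))
  r <- evaluatePath(pred, ref)
  expect_equal(r@kappa, cohenKappa(r@confusion))
  expect_identical(r@agreement, interpretKappa(r@kappa))
  # copying the reference gives kappa exactly 1
  expect_equal(evaluatePath(ref, ref)@kappa, 1)
  expect_error(evaluatePath(sample(1:4, 10, TRUE), ref[1:10]), "arity")
})

test_that("reference label rules select the documented frames and labels", {
  ann <- rbind(c("ok", "ok", "ok"), c("no_ok", "no_ok", "no_ok"),
               c("ok", "no_ok", "ok"), c("no_ok", "no_ok", "ok"),
               c("ok", "ok", "no_ok"))
  rel <- referenceLabels("reliable", ann)
  expect_equal(rel$idx, c(1L, 2L))
  expect_equal(rel$labels, c("ok", "no_ok"))
  maj <- referenceLabels("majority", ann)
  expect_equal(maj$labels, c("ok", "no_ok", "ok", "no_ok", "ok"))
  grp <- referenceLabels("group", ann)
  expect_equal(grp$labels, c(4L, 1L, 2L, 3L, 2L))
  # a group-2 frame has binary reference ok; (no_ok, no_ok, ok) is group 3
  expect_equal(maj$labels[3], "ok")
  expect_equal(grp$labels[4], 3L)
  e2 <- referenceLabels("expert2", ann)
  expect_equal(e2$labels, ann[, 2], ignore_attr = TRUE)
  expect_error(referenceLabels("oracle", ann), "unknown reference rule")
})

test_that("the numbered evaluation plans map to paths and rules", {
  expect_equal(evaluationPlan(1), list(path = 1L, rule = "reliable"))
  expect_equal(evaluationPlan(2), list(path = 1L, rule = "majority"))
  expect_equal(evaluationPlan(6), list(path = 4L, rule = "majority"))
  expect_equal(evaluationPlan(7), list(path = 5L, rule = "group"))
  expect_equal(evaluationPlan(10), list(path = 8L, rule = "group"))
  expect_true(is.na(evaluationPlan(4)$path))
  expect_error(evaluationPlan(11), "unknown evaluation")
})
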