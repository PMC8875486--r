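# Small random frames for engine-level checks (any input size works; the
# conv stacks are fully convolutional and the head is GAP + dense).
smallFrames <- function(n, size = 32, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    array(sample(0:255, size * size * 3, TRUE), c(size, size, 3)))
}

test_that("backbone architectures carry the documented freeze configuration", {
  m <- buildModel(trainConfig("vgg16", nClasses = 2))
  tab <- modelLayerTable(m)
  expect_equal(sum(tab$type == "conv"), 13)
  expect_equal(sum(tab$type == "conv" & !tab$trainable), 10)
  frozen <- tab$conv_index[tab$type == "conv" & !tab$trainable]
  expect_equal(sort(frozen), 1:10)        # the *first* 10 in definition order

  md <- buildModel(trainConfig("densenet201"))
  tabd <- modelLayerTable(md)
  expect_equal(sum(tabd$type == "conv"), 200)
  expect_equal(sum(tabd$type == "conv" & !tabd$trainable), 140)

  mt <- buildModel(trainConfig("tiny_test"))
  tabt <- modelLayerTable(mt)
  expect_true(all(tabt$trainable[tabt$type == "conv"]))

  expect_error(buildModel(trainConfig("vgg16", frozenConvLayers = 14)),
               "cannot freeze")
  expect_error(buildModel(list(backbone = "alexnet", nClasses = 2,
                               frozenConvLayers = 0, seed = 1)), "unknown backbone")
})

test_that("frozen conv parameters are bit-identical after training", {
  frames <- smallFrames(6)
  labels <- rep(c("ok", "no_ok"), 3)
  for (bb in c("vgg16", "densenet201")) {
    cfg <- trainConfig(bb, seed = 3, batchSize = 6L)
    m0 <- buildModel(cfg)
    m1 <- trainModel(m0, frames, labels, epochs = 1)
    tab <- modelLayerTable(m1)
    frozenIdx <- which(tab$type == "conv" & !tab$trainable)
    trainableIdx <- which(tab$type == "conv" & tab$trainable)
    for (l in frozenIdx)
      expect_identical(m1@layers[[l]]$W, m0@layers[[l]]$W)
    expect_true(any(vapply(trainableIdx, function(l)
      !identical(m1@layers[[l]]$W, m0@layers[[l]]$W), logical(1))))
  }
})

test_that("training is deterministic given the seed and logs one row per epoch", {
  frames <- smallFrames(8)
  labels <- rep(c("ok", "no_ok"), 4)
  cfg <- trainConfig("tiny_test", seed = 11)
  m1 <- trainModel(buildModel(cfg), frames, labels, epochs = 3)
  m2 <- trainModel(buildModel(cfg), frames, labels, epochs = 3)
  expect_identical(m1@layers, m2@layers)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_equal(nrow(trainingLog(m1)), 3)
  # epochs = 0 returns the model unchanged with an empty log
  m0 <- buildModel(cfg)
  mu <- trainModel(m0, frames, labels, epochs = 0)
  expect_identical(mu@layers, m0@layers)
  expect_equal(nrow(trainingLog(mu)), 0)
})

test_that("training validates its inputs", {
  cfg <- trainConfig("tiny_test")
  m <- buildModel(cfg)
  expect_error(trainModel(m, list(), character(0)), "empty training set")
  expect_error(trainModel(m, smallFrames(4), rep("ok", 3)), "differ in length")
  expect_error(trainModel(m, smallFrames(4), c("ok", "no_ok", "good", "ok")),
               "outside the model's classes")
  m4 <- buildModel(trainConfig("tiny_test", nClasses = 4))
  expect_warning(trainModel(m4, smallFrames(4), c(1, 1, 2, 2), epochs = 1),
                 "cover only")
})

test_that("predicted score vectors are normalized and deterministic", {
  frames <- smallFrames(5, seed = 2)
  m <- trainModel(buildModel(trainConfig("tiny_test", seed = 4)),
                  frames, c("ok", "ok", "no_ok", "no_ok", "ok"), epochs = 2)
  sc <- predictScores(m, frames)
  expect_equal(dim(sc), c(5L, 2L))
  expect_equal(colnames(sc), binaryLevels())
  expect_equal(rowSums(sc), rep(1, 5))
  expect_true(all(sc >= 0 & sc <= 1))
  # a duplicated frame scores identically
  sc2 <- predictScores(m, frames[c(1, 1)])
  expect_identical(sc2[1, ], sc2[2, ])
})

test_that("the ok-probability is the ok-class score with the complement law", {
  sc <- matrix(c(0.2, 0.8, 1, 0), 2, byrow = TRUE,
               dimnames = list(NULL, c("no_ok", "ok")))
  expect_equal(scoreToOkProbability(sc), c(0.8, 0))
  expect_equal(scoreToOkProbability(sc) + sc[, "no_ok"], c(1, 1),
               ignore_attr = TRUE)
  expect_error(scoreToOkProbability(matrix(0.25, 1, 4)), "binary")
})

test_that("tiny_test separates the constructed classes on held-out frames", {
  set.seed(50)
  mkSet <- function(n, seed) {
    set.seed(seed)
    cls <- c(rep("correct", n / 2),
             sample(c("no_contact", "low_contrast", "geometry_artifact", "shadow"),
                    n / 2, replace = TRUE))
    list(frames = lapply(cls, function(cl) generateFrame(cl)$pixels),
         labels = rep(c("ok", "no_ok"), each = n / 2))
  }
  train <- mkSet(60, 601)
  test <- mkSet(30, 602)
  m <- trainModel(buildModel(trainConfig("tiny_test", seed = 9)),
                  train$frames, train$labels, epochs = 5)
  trainAcc <- mean(thresholdBinary(scoreToOkProbability(
    predictScores(m, train$frames))) == train$labels)
  testAcc <- mean(thresholdBinary(scoreToOkProbability(
    predictScores(m, test$frames))) == test$labels)
  expect_gt(trainAcc, 0.9)
  expect_gt(testAcc, 0.9)
})

test_that("model checkpoints survive a save/load round-trip", {
  frames <- smallFrames(4)
  m <- trainModel(buildModel(trainConfig("tiny_test", seed = 2)),
                  frames, c("ok", "no_ok", "ok", "no_ok"), epochs = 1)
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, tmp)
  back <- loadModel(tmp)
  expect_identical(predictScores(back, frames), predictScores(m, frames))
})
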