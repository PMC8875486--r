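test_that("group assignment matches the consensus scheme on all combinations", {
  combos <- allTripleCombos()
  g <- assignGroup(combos)
  # preimage sizes 1, 3, 3, 1 for groups 1..4
  expect_equal(as.integer(table(factor(g, levels = 1:4))), c(1L, 3L, 3L, 1L))
  expect_equal(assignGroup(c("no_ok", "no_ok", "no_ok")), 1L)
  expect_equal(assignGroup(c("ok", "no_ok", "ok")), 2L)
  expect_equal(assignGroup(c("no_ok", "ok", "no_ok")), 3L)
  expect_equal(assignGroup(c("ok", "ok", "ok")), 4L)
})

test_that("group-to-binary collapse agrees with majority voting everywhere", {
  combos <- allTripleCombos()
  expect_identical(groupToBinary(assignGroup(combos)), majorityVote(combos))
  expect_identical(groupToBinary(c(4L, 3L, 2L, 1L)), c("ok", "no_ok", "ok", "no_ok"))
})

test_that("majority voting needs an odd number of votes", {
  expect_identical(majorityVote(c("ok", "ok", "no_ok")), "ok")
  expect_identical(majorityVote(rep("no_ok", 3)), "no_ok")
  expect_error(majorityVote(c("ok", "no_ok")), "odd")
})

test_that("confusion counts match brute-force tallying", {
  expect_equal(unname(confusionCounts(c("ok", "no_ok"), c("ok", "no_ok"),
                                      binaryLevels())),
               diag(c(1L, 1L)))
  m <- confusionCounts(c("ok", "ok"), c("no_ok", "no_ok"), binaryLevels())
  expect_equal(sum(diag(m)), 0L)
  expect_equal(sum(m), 2L)
  set.seed(31)
  a <- sample(binaryLevels(), 100, replace = TRUE)
  b <- sample(binaryLevels(), 100, replace = TRUE)
  m <- confusionCounts(a, b, binaryLevels())
  for (i in 1:2) for (j in 1:2)
    expect_equal(m[i, j], sum(a == binaryLevels()[i] & b == binaryLevels()[j]))
  expect_error(confusionCounts(a, b[-1]), "length")
})

test_that("Cohen's kappa matches an independent formula evaluation", {
  expect_equal(cohenKappa(diag(c(50, 50))), 1)
  expect_equal(cohenKappa(matrix(c(40, 5, 10, 45), 2)), 0.70)
  expect_equal(cohenKappa(matrix(25, 2, 2)), 0)
  set.seed(77)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    m <- matrix(rpois(k * k, lambda = sample(1:30, 1)) + 1, k, k)
    expect_equal(cohenKappa(m), referenceKappa(m), tolerance = 1e-12)
  }
})

test_that("kappa is transpose-symmetric, 1 on diagonals, scale-invariant", {
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2, 2)
    expect_equal(cohenKappa(m), cohenKappa(t(m)))
    expect_equal(cohenKappa(3 * m), cohenKappa(m))
  }
  expect_equal(cohenKappa(diag(c(3, 9, 1))), 1)
  expect_error(cohenKappa(matrix(0, 2, 2)), "empty")
  # degenerate: single category used by both raters, perfect -> 1
  expect_equal(cohenKappa(matrix(c(10, 0, 0, 0), 2)), 1)
  # one-sided disagreement: chance agreement 0, kappa 0
  expect_equal(cohenKappa(matrix(c(0, 10, 0, 0), 2)), 0)
})

test_that("kappa bands reproduce the published category calls", {
  expect_identical(interpretKappa(0.8322), "Perfect")
  expect_identical(interpretKappa(0.7822), "Substantial")
  expect_identical(interpretKappa(0.7193), "Substantial")
  expect_identical(interpretKappa(0.8214), "Perfect")
})

test_that("kappa interpretation is a total step function without gaps", {
  ks <- seq(-1, 1, by = 0.001)
  cats <- interpretKappa(ks)
  expect_true(all(cats %in% c("Poor", "Slight", "Fair", "Moderate",
                              "Substantial", "Perfect")))
  # band edges: closed on the right
  expect_identical(interpretKappa(c(-1e-9, 0, 0.2, 0.200001, 0.4, 0.6, 0.8, 1)),
                   c("Poor", "Slight", "Slight", "Fair", "Fair", "Moderate",
                     "Substantial", "Perfect"))
  expect_error(interpretKappa(1.2), "\\[-1, 1\\]")
})

test_that("group size summary and discordant fraction are conserved", {
  triples <- do.call(rbind, rep(list(c("ok", "ok", "ok")), 10))
  expect_equal(unname(groupSizeSummary(triples)), c(0L, 0L, 0L, 10L))
  set.seed(9)
  m <- matrix(sample(binaryLevels(), 300, replace = TRUE), ncol = 3)
  counts <- groupSizeSummary(m)
  expect_equal(sum(counts), 100L)
  expect_equal(discordantFraction(counts),
               sum(assignGroup(m) %in% c(2, 3)) / 100)
})

test_that("published group sizes give the reported totals and ratios", {
  sizes <- c(8398, 1261, 1324, 6442)
  expect_equal(sum(sizes), 17425)
  expect_equal(discordantFraction(sizes), (1261 + 1324) / 17425)
  expect_equal(round(discordantFraction(sizes), 3), 0.148)
})

test_that("pairwise agreement reports are consistent", {
  ann <- cbind(rep("ok", 10), rep("ok", 10), rep("ok", 10))
  reps <- pairwiseAgreement(rbind(ann, matrix("no_ok", 5, 3)))
  for (r in reps) {
    expect_s4_class(r, "AgreementReport")
    expect_equal(r@kappa, 1)
    expect_identical(r@category, "Perfect")
  }
  df <- agreementAsDataFrame(reps[[1]])
  expect_equal(df$ok_ok + df$no_ok_no_ok + df$ok_no_ok + df$no_ok_ok, 15)
})
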