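test_that("frame file names parse into their three tokens", {
  expect_equal(parseFrameFilename("p07_loc2_0012.png"),
               c(patient_id = "07", facial_location = "loc2", image_id = "0012"))
  expect_equal(unname(parseFrameFilename("p7_A_1.png")), c("7", "A", "1"))
  expect_error(parseFrameFilename("frame01.png"), "malformed.*frame01")
  expect_error(parseFrameFilename("p1_a_b_c.png"), "malformed")
  expect_error(parseFrameFilename("x1_a_1.png"), "malformed")
  expect_error(parseFrameFilename("p1_a_1.jpg"), "malformed")
})

test_that("annotation tables read, normalize and validate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("File_name,Expert 1,Expert 2,Expert 3",
               "p1_a_1.png,ok,ok,ok",
               "p1_a_2.png,OK ,no ok,NO_OK",
               "p1_a_3.png,1,0, no  ok"), tmp)
  rows <- readAnnotationTable(tmp)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$expert1, c("ok", "ok", "ok"))
  expect_equal(rows$expert2, c("ok", "no_ok", "no_ok"))
  expect_equal(rows$expert3, c("ok", "no_ok", "no_ok"))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("File_name,Expert 1,Expert 2,Expert 3", empty)
  expect_equal(nrow(readAnnotationTable(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("File_name,Expert 1,Expert 2,Expert 3",
               "p1_a_1.png,ok,maybe,ok"), bad)
  expect_error(readAnnotationTable(bad), "unknown label token 'maybe'")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("File_name,Expert 1,Expert 2,Expert 3",
               "p1_a_1.png,ok,ok,ok", "p1_a_1.png,ok,ok,ok"), dup)
  expect_error(readAnnotationTable(dup), "duplicate")
})

test_that("annotation write-then-read is the identity on normalized rows", {
  rows <- data.frame(file_name = c("p1_a_1.png", "p2_b_2.png"),
                     expert1 = c("ok", "no_ok"), expert2 = c("ok", "ok"),
                     expert3 = c("no_ok", "no_ok"), stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeAnnotationTable(rows, tmp)
  expect_equal(readAnnotationTable(tmp), rows)
})

test_that("frames load as 224 x 224 x 3 regardless of input size and depth", {
  tmp <- withr::local_tempdir()
  # identity on an already-conformant RGB image
  px <- array(as.integer(sample(0:255, 224 * 224 * 3, TRUE)), c(224, 224, 3))
  f1 <- file.path(tmp, "p1_a_1.png")
  png::writePNG(px / 255, f1)
  expect_identical(loadFrame(f1), px)
  # single-channel tall image (original scanner aspect) downsampled
  f2 <- file.path(tmp, "p1_a_2.png")
  png::writePNG(matrix(runif(693 * 1733), 693, 1733), f2)
  out <- loadFrame(f2)
  expect_identical(dim(out), c(224L, 224L, 3L))
  expect_identical(out[, , 1], out[, , 3])       # grayscale replicated
  # tiny image upsampled
  f3 <- file.path(tmp, "p1_a_3.png")
  png::writePNG(matrix(runif(100), 10, 10), f3)
  expect_identical(dim(loadFrame(f3)), c(224L, 224L, 3L))
  expect_error(loadFrame(file.path(tmp, "missing.png")), "cannot read")
})

test_that("datasets round-trip through the on-disk session layout", {
  cfg <- syntheticConfig(nFrames = 24, seed = 303)
  ds <- generateDataset(cfg)
  root <- withr::local_tempdir()
  writeDataset(ds, root)
  back <- loadDataset(root)
  expect_equal(nFrames(back), 24)
  # annotations identical after matching on file name
  ord <- match(frameInfo(ds)$file_name, frameInfo(back)$file_name)
  expect_false(anyNA(ord))
  expect_equal(unname(annotations(back)[ord, ]), unname(annotations(ds)))
  # pixels identical (PNG is lossless, frames already 224x224)
  i <- which(ord == 1)[1]
  expect_identical(framePixels(back, 1), framePixels(ds, ord[1]))
  expect_equal(sort(unique(frameInfo(back)$session_id)), sort(cfg$sessionIds))
})

test_that("annotation/image mismatches are reported with the offending files", {
  ds <- generateDataset(syntheticConfig(nFrames = 20, seed = 7))
  root <- withr::local_tempdir()
  writeDataset(ds, root)
  sdir <- file.path(root, frameInfo(ds)$session_id[1])
  victim <- frameInfo(ds)$file_name[1]
  unlink(file.path(sdir, victim))
  expect_error(loadDataset(root), victim, fixed = TRUE)
})

test_that("the dataset container enforces its invariants", {
  ds <- generateDataset(syntheticConfig(nFrames = 20, seed = 1), pixels = FALSE)
  expect_equal(nFrames(ds), 20)
  sub <- ds[1:5]
  expect_equal(nFrames(sub), 5)
  expect_equal(annotations(sub), annotations(ds)[1:5, ])
  info <- frameInfo(ds)
  dupInfo <- info
  dupInfo[2, c("patient_id", "facial_location", "image_id", "session_id")] <-
    dupInfo[1, c("patient_id", "facial_location", "image_id", "session_id")]
  expect_error(hfusDataset(dupInfo, annotations(ds)), "unique")
  expect_error(hfusDataset(info, annotations(ds)[, 1:2]), "3 columns|3 expert")
})
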