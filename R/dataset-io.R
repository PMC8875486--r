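#' Parse an HFUS frame file name
#'
#' File names follow the pattern \code{pPatientID_FacialLocation_ImageID.png}:
#' a leading \code{"p"}, three tokens separated by exactly two underscores,
#' and a \code{.png} suffix. Tokens are returned verbatim (no numeric
#' coercion).
#'
#' @param name file name (a single string).
#' @return named character vector with elements \code{patient_id},
#'   \code{facial_location}, \code{image_id}.
#' @examples
#' parseFrameFilename("p07_loc2_0012.png")
#' @export
parseFrameFilename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^p([^_]+)_([^_]+)_([^_]+)\\.png$", name))[[1]]
  if (length(m) != 4L)
    stop(sprintf("malformed frame file name: '%s' (expected pPatientID_FacialLocation_ImageID.png)",
                 name), call. = FALSE)
  c(patient_id = m[2], facial_location = m[3], image_id = m[4])
}

## Label-token normalization map (case/whitespace-insensitive).
.normalizeLabels <- function(x, where = "annotation table") {
  key <- gsub("[[:space:]_]+", "", tolower(trimws(as.character(x))))
  map <- c(ok = "ok", nook = "no_ok", "1" = "ok", "0" = "no_ok")
  out <- map[key]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unknown label token '%s' at entry %d of %s",
                 as.character(x)[bad], bad, where), call. = FALSE)
  }
  unname(out)
}

#' Read a per-session annotation table
#'
#' Accepts CSV (canonical) and XLS/XLSX (requires the readxl package). The
#' table must carry a file-name column followed by the three expert label
#' columns; headers are matched case-insensitively against
#' \code{File_name, Expert 1, Expert 2, Expert 3} (separators ignored), and
#' otherwise the first four columns are taken positionally. Label cells are
#' normalized to \code{ok}/\code{no_ok}; accepted tokens are \code{ok},
#' \code{no ok}, \code{no_ok}, \code{1}, \code{0} in any case/whitespace.
#'
#' @param path path to the table.
#' @return data.frame with columns \code{file_name, expert1, expert2,
#'   expert3}, row order preserved.
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation table not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xls", "xlsx")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLS/XLSX annotation tables requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"))
  } else {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  }
  if (ncol(df) < 4L)
    stop(sprintf("annotation table %s needs a file-name column and three expert columns", path))
  norm <- gsub("[[:space:]_.]+", "", tolower(names(df)))
  fileCol <- match(TRUE, norm %in% c("filename", "file"))
  expCols <- match(c("expert1", "expert2", "expert3"), norm)
  if (is.na(fileCol) || anyNA(expCols)) {
    fileCol <- 1L
    expCols <- 2:4
  }
  out <- data.frame(file_name = trimws(df[[fileCol]]), stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    out$expert1 <- out$expert2 <- out$expert3 <- character(0)
    return(out)
  }
  dup <- duplicated(out$file_name)
  if (any(dup))
    stop(sprintf("duplicate file_name '%s' in %s", out$file_name[dup][1], path))
  for (i in 1:3) {
    out[[paste0("expert", i)]] <-
      .normalizeLabels(df[[expCols[i]]],
                       where = sprintf("column %d of %s", expCols[i], basename(path)))
  }
  out
}

#' Write an annotation table (CSV)
#'
#' Inverse of [readAnnotationTable()] on normalized rows: labels are written
#' with the annotators' original tokens (\code{ok} / \code{no ok}) under the
#' headers \code{File_name, Expert 1, Expert 2, Expert 3}.
#'
#' @param rows data.frame with columns \code{file_name, expert1..3}
#'   (normalized labels).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationTable <- function(rows, path) {
  stopifnot(all(c("file_name", "expert1", "expert2", "expert3") %in% names(rows)))
  pretty <- function(x) ifelse(x == "ok", "ok", "no ok")
  out <- data.frame(`File_name` = rows$file_name,
                    `Expert 1` = pretty(rows$expert1),
                    `Expert 2` = pretty(rows$expert2),
                    `Expert 3` = pretty(rows$expert3),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Load a single HFUS frame
#'
#' Reads a PNG, drops any alpha channel, replicates grayscale to three
#' channels, and resamples (bilinear) to 224 x 224. Pixel values are
#' returned as integers in [0, 255].
#'
#' @param path PNG file path.
#' @return integer array of dimension 224 x 224 x 3.
#' @export
loadFrame <- function(path) {
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) stop(sprintf("cannot read image '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  dat <- EBImage::imageData(img)                 # EBImage layout: (x, y[, ch])
  d <- dim(dat)
  if (length(d) == 3L && d[3] == 4L) dat <- dat[, , 1:3]           # drop alpha
  if (length(d) == 3L && d[3] == 2L) dat <- dat[, , 1L]            # gray+alpha
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  if (dim(dat)[1] != 224L || dim(dat)[2] != 224L) {
    dat <- EBImage::imageData(EBImage::resize(EBImage::Image(dat, colormode = "Color"),
                                              w = 224L, h = 224L))
  }
  dat <- aperm(dat, c(2L, 1L, 3L))               # back to (row, col, channel)
  px <- array(as.integer(round(pmin(pmax(dat, 0), 1) * 255)), c(224L, 224L, 3L))
  px
}

#' Construct an HfusDataset
#'
#' @param frameInfo data.frame with at least \code{file_name, patient_id,
#'   facial_location, image_id, session_id}.
#' @param annotations n x 3 matrix of \code{ok}/\code{no_ok} labels.
#' @param pixels list of n pixel arrays (224 x 224 x 3 integers) or NULLs.
#' @return an \linkS4class{HfusDataset}.
#' @export
hfusDataset <- function(frameInfo, annotations, pixels = NULL) {
  annotations <- .asTripleMatrix(annotations)
  colnames(annotations) <- paste0("Expert", 1:3)
  if (is.null(pixels)) pixels <- vector("list", nrow(frameInfo))
  new("HfusDataset", frameInfo = as.data.frame(frameInfo),
      annotations = annotations, pixels = pixels)
}

#' @describeIn hfusDataset number of frames.
#' @param ds an \linkS4class{HfusDataset}.
#' @export
nFrames <- function(ds) nrow(ds@frameInfo)

#' @describeIn hfusDataset per-frame metadata data.frame.
#' @export
frameInfo <- function(ds) ds@frameInfo

#' @describeIn hfusDataset n x 3 annotation matrix.
#' @export
annotations <- function(ds) ds@annotations

#' @describeIn hfusDataset pixels of frame \code{i} (integer 224 x 224 x 3).
#' @param i frame index.
#' @export
framePixels <- function(ds, i) ds@pixels[[i]]

#' @describeIn hfusDataset subset the dataset by frame index.
#' @param x an \linkS4class{HfusDataset}.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "HfusDataset", function(x, i, j, ..., drop = FALSE) {
  hfusDataset(x@frameInfo[i, , drop = FALSE],
              x@annotations[i, , drop = FALSE],
              x@pixels[i])
})

#' Load an HFUS dataset from its on-disk layout
#'
#' The layout mirrors the published repository: one folder per acquisition
#' session (named by its day-month-year ID), each containing the PNG frames
#' and one annotation table named \code{<ID>_DataDesc.{csv,xls,xlsx}}. Every
#' annotation row must match a frame on disk and vice versa.
#'
#' @param root dataset root directory.
#' @param loadPixels load the pixel arrays (default TRUE); with FALSE only
#'   the metadata and labels are read.
#' @return an \linkS4class{HfusDataset} with frames of all sessions paired
#'   to their annotation rows.
#' @export
loadDataset <- function(root, loadPixels = TRUE) {
  if (!dir.exists(root)) stop(sprintf("dataset root not found: %s", root))
  sessions <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  if (length(sessions) == 0L) stop(sprintf("no session folders under %s", root))
  infoList <- list(); annList <- list(); pixList <- list()
  for (sdir in sessions) {
    sid <- basename(sdir)
    tables <- list.files(sdir, pattern = "_DataDesc\\.(csv|xls|xlsx)$",
                         full.names = TRUE, ignore.case = TRUE)
    if (length(tables) != 1L)
      stop(sprintf("session %s must contain exactly one *_DataDesc table (found %d)",
                   sid, length(tables)))
    rows <- readAnnotationTable(tables[1])
    pngs <- list.files(sdir, pattern = "\\.png$", ignore.case = TRUE)
    missingPng <- setdiff(rows$file_name, pngs)
    unlabeled <- setdiff(pngs, rows$file_name)
    if (length(missingPng) || length(unlabeled))
      stop(sprintf(paste0("session %s: annotation/image mismatch; rows without image: [%s];",
                          " images without row: [%s]"),
                   sid, paste(missingPng, collapse = ", "),
                   paste(unlabeled, collapse = ", ")))
    ids <- t(vapply(rows$file_name, parseFrameFilename, character(3)))
    infoList[[sid]] <- data.frame(file_name = rows$file_name,
                                  patient_id = ids[, 1], facial_location = ids[, 2],
                                  image_id = ids[, 3], session_id = sid,
                                  stringsAsFactors = FALSE, row.names = NULL)
    annList[[sid]] <- as.matrix(rows[, c("expert1", "expert2", "expert3")])
    pixList[[sid]] <- if (loadPixels) {
      lapply(file.path(sdir, rows$file_name), loadFrame)
    } else vector("list", nrow(rows))
  }
  hfusDataset(do.call(rbind, c(infoList, list(make.row.names = FALSE))),
              do.call(rbind, annList),
              do.call(c, pixList))
}
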