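## Synthetic HFUS frames and simulated annotators. The emulation is
## statistical, not physical: a correct B-mode frame is modelled as a bright
## entry-echo band in the upper quarter over depth-attenuated tissue with
## multiplicative gamma speckle; the incorrect classes reproduce the failure
## taxonomy (no probe contact, low contrast, disturbed geometry, acoustic
## shadowing) at a severity tied to a latent quality score in [0,1].

SYNTH_CLASSES <- c("correct", "no_contact", "low_contrast",
                   "geometry_artifact", "shadow")

#' Synthetic dataset configuration
#'
#' Defaults emulate the published cohort: group proportions from the
#' reported group sizes (8398/1261/1324/6442 of 17,425 frames), an
#' ambiguous (discordant) fraction of ~0.148, and three annotators whose
#' label-flip rates act only near the quality boundary. Experts 1 and 2
#' share a flip rate (they are the same person annotating twice) but use
#' independent randomness.
#'
#' @param nFrames number of frames (at least 20).
#' @param groupProportions length-4 proportions of the fused groups 1..4;
#'   must sum to 1.
#' @param flipRates per-annotator flip rates in [0, 0.5).
#' @param ambiguityFraction expected discordant fraction; defaults to the
#'   sum of the group-2 and group-3 proportions.
#' @param sessionIds session folder names (day-month-year style tokens).
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @return a named list (validated).
#' @export
syntheticConfig <- function(nFrames = 600L,
                            groupProportions = c(8398, 1261, 1324, 6442) / 17425,
                            flipRates = c(0.3, 0.3, 0.3),
                            ambiguityFraction = NULL,
                            sessionIds = c("08032021", "15022021"),
                            seed = 1L) {
  groupProportions <- as.numeric(groupProportions)
  if (length(groupProportions) != 4L)
    stop("groupProportions must have length 4")
  if (abs(sum(groupProportions) - 1) > 1e-9)
    stop("groupProportions must sum to 1")
  if (length(flipRates) != 3L) stop("flipRates must have length 3")
  if (any(flipRates < 0) || any(flipRates >= 0.5))
    stop("flipRates must lie in [0, 0.5)")
  if (is.null(ambiguityFraction))
    ambiguityFraction <- groupProportions[2] + groupProportions[3]
  list(nFrames = as.integer(nFrames), groupProportions = groupProportions,
       flipRates = as.numeric(flipRates),
       ambiguityFraction = as.numeric(ambiguityFraction),
       sessionIds = as.character(sessionIds), seed = as.integer(seed))
}

#' Ambiguity weight of a quality score
#'
#' The annotator flip probability is \code{flipRate * qualityAmbiguityWeight(q)}:
#' a quadratic bump that is 1 at the decision boundary q = 0.5, falls to 0
#' at |q - 0.5| = 0.35 and stays 0 towards the extremes, so unambiguous
#' frames are never mislabelled.
#'
#' @param q numeric vector of quality scores in [0,1].
#' @return weights in [0,1].
#' @export
qualityAmbiguityWeight <- function(q) {
  if (any(q < 0) || any(q > 1)) stop("quality must lie in [0,1]")
  pmax(0, 1 - ((q - 0.5) / 0.35)^2)
}

#' Simulate the three expert annotations of frames
#'
#' The nominal label is ok iff quality >= 0.5; annotator i flips it with
#' probability \code{flipRates[i] * qualityAmbiguityWeight(q)}, so only
#' frames near the boundary are ambiguous. Uses the current RNG stream.
#'
#' @param quality numeric vector of latent quality scores in [0,1].
#' @param flipRates length-3 flip rates in [0, 0.5).
#' @return n x 3 character matrix of \code{ok}/\code{no_ok} labels.
#' @export
simulateAnnotators <- function(quality, flipRates = c(0.3, 0.3, 0.3)) {
  if (length(flipRates) != 3L || any(flipRates < 0) || any(flipRates >= 0.5))
    stop("flipRates must be 3 values in [0, 0.5)")
  n <- length(quality)
  b <- qualityAmbiguityWeight(quality)
  nominal <- ifelse(quality >= 0.5, "ok", "no_ok")
  out <- matrix("", n, 3L, dimnames = list(NULL, paste0("Expert", 1:3)))
  for (i in 1:3) {
    flip <- stats::runif(n) < flipRates[i] * b
    out[, i] <- ifelse(flip, ifelse(nominal == "ok", "no_ok", "ok"), nominal)
  }
  out
}

## ---- frame synthesis -------------------------------------------------------

.correctFrame <- function(q, bandCenter = 34, tilt = 0) {
  h <- w <- 224L
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  center <- bandCenter + tilt * (cc - w / 2)
  band <- 205 * exp(-((r - center) / 9)^2)
  tissueTop <- center + 14
  tissue <- ifelse(r > tissueTop, 95 * exp(-(r - tissueTop) / 320), 0)
  img <- 16 + band + tissue
  speckle <- matrix(stats::rgamma(h * w, shape = 4, rate = 4), h, w)
  img <- ifelse(r > tissueTop, img * speckle, img)
  img + matrix(stats::rnorm(h * w, sd = 4), h, w)
}

.compressContrast <- function(img, q) {
  cfac <- 1 + 6 * (1 - q)
  m <- mean(img)
  m + (img - m) / cfac
}

#' Generate one synthetic HFUS frame
#'
#' Classes: \code{correct} draws a bright horizontal entry-echo band in the
#' upper quarter over speckled tissue; \code{no_contact} is near-uniform
#' low-intensity noise with no band; \code{low_contrast} is the correct
#' pattern with its dynamic range compressed (at least 4-fold for clearly
#' bad frames); \code{geometry_artifact} tilts the band by more than 20
#' degrees (and may break it); \code{shadow} adds a dark vertical wedge.
#' Severity scales with \code{1 - quality}. Deterministic given the RNG
#' state.
#'
#' @param class one of \code{correct, no_contact, low_contrast,
#'   geometry_artifact, shadow}.
#' @param quality latent quality in [0,1]; defaults to a class-typical draw.
#' @return list with \code{pixels} (integer 224 x 224 x 3 array, values
#'   0..255), \code{class} and \code{quality}.
#' @export
generateFrame <- function(class, quality = NULL) {
  if (!class %in% SYNTH_CLASSES)
    stop(sprintf("unknown synthetic class '%s'", class))
  if (is.null(quality)) {
    quality <- switch(class,
      correct = stats::runif(1, 0.72, 0.97),
      no_contact = stats::runif(1, 0.02, 0.08),
      stats::runif(1, 0.15, 0.30))
  }
  img <- switch(class,
    correct = .correctFrame(quality),
    no_contact = matrix(12 + stats::rnorm(224 * 224, sd = 5), 224, 224),
    low_contrast = .compressContrast(.correctFrame(quality), quality),
    geometry_artifact = {
      tiltDeg <- 22 + 30 * (1 - quality)
      base <- .correctFrame(quality, tilt = tanpi(tiltDeg / 180))
      if (stats::runif(1) < 0.5) {       # broken band: zero out column gaps
        gapStart <- sample.int(150, 1)
        gapW <- 30 + sample.int(40, 1)
        mask <- matrix(1, 224, 224)
        mask[1:60, gapStart:min(224, gapStart + gapW)] <- 0.1
        base <- base * mask
      }
      base
    },
    shadow = {
      base <- .correctFrame(quality)
      w0 <- (0.15 + 0.5 * (1 - quality)) * 224
      centerCol <- 60 + stats::runif(1) * 104
      r <- matrix(seq_len(224), 224, 224)
      cc <- matrix(seq_len(224), 224, 224, byrow = TRUE)
      halfw <- (w0 / 2) * (0.3 + 0.7 * pmax(0, r - 48) / 176)
      att <- ifelse(abs(cc - centerCol) < halfw & r > 48, 0.15, 1)
      base * att
    })
  px <- pmin(pmax(img, 0), 255)
  pixels <- array(as.integer(round(px)), c(224L, 224L, 3L))
  list(pixels = pixels, class = class, quality = quality)
}

## Draw a class and quality consistent with the intended fused group.
.classQualityForGroup <- function(g) {
  badClasses <- c("no_contact", "low_contrast", "geometry_artifact", "shadow")
  midClasses <- c("low_contrast", "geometry_artifact", "shadow")
  switch(as.character(g),
    "1" = {
      cl <- sample(badClasses, 1)
      q <- if (cl == "no_contact") stats::runif(1, 0.02, 0.08)
           else stats::runif(1, 0.15, 0.30)
      list(class = cl, quality = q)
    },
    "2" = list(class = sample(midClasses, 1), quality = stats::runif(1, 0.52, 0.64)),
    "3" = list(class = sample(midClasses, 1), quality = stats::runif(1, 0.36, 0.48)),
    "4" = list(class = "correct", quality = stats::runif(1, 0.72, 0.97)))
}

## Annotation triple conditioned on the intended group: rejection-sample the
## flip mechanism until the realized group matches (cap 200 tries). When the
## flip rates make the intended group unreachable (e.g. zero rates with a
## discordant group drawn) the unanimous nominal labels are kept.
.annotateForGroup <- function(g, quality, flipRates, cap = 200L) {
  reachable <- !(g %in% c(2L, 3L)) ||
    max(flipRates) * qualityAmbiguityWeight(quality) > 0
  if (reachable) {
    for (t in seq_len(cap)) {
      tri <- simulateAnnotators(quality, flipRates)
      if (assignGroup(tri[1, ]) == g) return(tri[1, ])
    }
  }
  nominal <- if (quality >= 0.5) "ok" else "no_ok"
  rep(nominal, 3L)
}

#' Generate a synthetic annotated HFUS dataset
#'
#' Draws the intended fused group of every frame from the configured
#' proportions, synthesizes a frame of a class/severity consistent with
#' that group, and simulates the three annotators conditioned on the
#' intended group (see the package vignette for the conditioning scheme).
#' With zero flip rates all annotations are unanimous and the discordant
#' fraction is 0.
#'
#' @param cfg a [syntheticConfig()].
#' @param dir optional output directory; when given, the on-disk layout of
#'   [loadDataset()] is written (one folder per session with PNG frames and
#'   a \code{<ID>_DataDesc.csv} table).
#' @param pixels synthesize pixel arrays (default TRUE); FALSE generates
#'   labels/metadata only (for large label-structure simulations).
#' @return an \linkS4class{HfusDataset}; \code{frameInfo()} additionally
#'   carries \code{true_quality}, \code{true_class} and \code{true_group}.
#' @export
generateDataset <- function(cfg = syntheticConfig(), dir = NULL, pixels = TRUE) {
  n <- cfg$nFrames
  if (n < 20L) stop("nFrames too small: need at least 20 frames for the fold machinery")
  set.seed(cfg$seed)
  groups <- sample.int(4L, n, replace = TRUE, prob = cfg$groupProportions)
  cls <- character(n); qual <- numeric(n)
  ann <- matrix("", n, 3L)
  pix <- vector("list", n)
  for (i in seq_len(n)) {
    cq <- .classQualityForGroup(groups[i])
    cls[i] <- cq$class; qual[i] <- cq$quality
    ann[i, ] <- .annotateForGroup(groups[i], cq$quality, cfg$flipRates)
    if (pixels) pix[[i]] <- generateFrame(cq$class, cq$quality)$pixels
  }
  nSess <- length(cfg$sessionIds)
  sess <- cfg$sessionIds[ceiling(seq_len(n) / ceiling(n / nSess))]
  patient <- sprintf("%02d", 1 + (seq_len(n) %% 8L))
  loc <- paste0("loc", 1 + (seq_len(n) %% 3L))
  imageId <- sprintf("%04d", seq_len(n))
  info <- data.frame(
    file_name = sprintf("p%s_%s_%s.png", patient, loc, imageId),
    patient_id = patient, facial_location = loc, image_id = imageId,
    session_id = sess, true_quality = qual, true_class = cls,
    true_group = groups, stringsAsFactors = FALSE)
  ds <- hfusDataset(info, ann, pix)
  if (!is.null(dir)) writeDataset(ds, dir)
  ds
}

#' Write a dataset in the on-disk session layout
#'
#' @param ds an \linkS4class{HfusDataset} with pixels loaded.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  info <- frameInfo(ds)
  ann <- annotations(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(info$session_id)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    idx <- which(info$session_id == sid)
    for (i in idx) {
      px <- framePixels(ds, i)
      if (is.null(px)) stop("cannot write a dataset without pixel arrays")
      png::writePNG(px / 255, file.path(sdir, info$file_name[i]))
    }
    writeAnnotationTable(
      data.frame(file_name = info$file_name[idx],
                 expert1 = ann[idx, 1], expert2 = ann[idx, 2],
                 expert3 = ann[idx, 3], stringsAsFactors = FALSE),
      file.path(sdir, paste0(sid, "_DataDesc.csv")))
  }
  invisible(dir)
}

#' Read / write a synthetic configuration as YAML
#'
#' @param path file path.
#' @export
readSyntheticConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(syntheticConfig, raw[intersect(names(raw),
    c("nFrames", "groupProportions", "flipRates", "ambiguityFraction",
      "sessionIds", "seed"))])
}

#' @rdname readSyntheticConfig
#' @param cfg a [syntheticConfig()].
#' @export
writeSyntheticConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
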