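#' Binary quality labels
#'
#' Frames are annotated as suitable for analysis (\code{"ok"}) or not
#' (\code{"no_ok"}). [binaryLevels()] returns the canonical class order used
#' throughout the package (no_ok first, ok second).
#'
#' @return character vector \code{c("no_ok", "ok")}.
#' @export
binaryLevels <- function() BINARY_LEVELS

.checkBinary <- function(x, what = "label") {
  if (!all(x %in% BINARY_LEVELS))
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(setdiff(x, BINARY_LEVELS)), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

.asTripleMatrix <- function(triples) {
  if (is.matrix(triples)) {
    if (ncol(triples) != 3L) stop("annotation triples must have 3 columns")
    m <- triples
  } else if (is.character(triples) && length(triples) == 3L) {
    m <- matrix(triples, nrow = 1L)
  } else if (is.data.frame(triples) && ncol(triples) == 3L) {
    m <- as.matrix(triples)
  } else stop("expected a length-3 label vector or an n x 3 label matrix")
  .checkBinary(m, "annotation")
  m
}

#' Fuse three expert labels into the four-group consensus label
#'
#' Group 1: all three experts said no_ok; group 2: exactly one no_ok;
#' group 3: exactly two no_ok; group 4: unanimous ok. The mapping is keyed
#' purely on the count of no_ok votes, so it is total on all 8 label
#' combinations.
#'
#' @param triples a length-3 character vector of \code{"ok"}/\code{"no_ok"},
#'   or an n x 3 matrix/data.frame of such labels (Expert 1..3).
#' @return integer vector of group labels in 1..4.
#' @seealso [groupToBinary()], [majorityVote()]
#' @examples
#' assignGroup(c("ok", "no_ok", "ok"))  # one dissenting no_ok -> group 2
#' @export
assignGroup <- function(triples) {
  m <- .asTripleMatrix(triples)
  nNo <- rowSums(m == "no_ok")
  # no_ok votes: 3 -> 1, 1 -> 2, 2 -> 3, 0 -> 4
  unname(c(`0` = 4L, `1` = 2L, `2` = 3L, `3` = 1L)[as.character(nNo)])
}

#' Collapse a group label to the majority binary label
#'
#' Groups 2 and 4 (majority ok) map to \code{"ok"}; groups 1 and 3
#' (majority no_ok) map to \code{"no_ok"}.
#'
#' @param g integer vector of group labels in 1..4.
#' @return character vector of binary labels.
#' @export
groupToBinary <- function(g) {
  if (!all(g %in% 1:4)) stop("group labels must be in 1..4")
  c("no_ok", "ok", "no_ok", "ok")[as.integer(g)]
}

#' Majority vote over an odd number of binary labels
#'
#' @param labels character vector (or n x k matrix for row-wise voting) of
#'   \code{"ok"}/\code{"no_ok"}; the number of votes must be odd so the
#'   result is always decided.
#' @return the winning label (vector of winners for matrix input).
#' @export
majorityVote <- function(labels) {
  if (is.matrix(labels)) {
    if (ncol(labels) %% 2L == 0L)
      stop("majority voting requires an odd number of votes")
    .checkBinary(labels, "vote")
    return(ifelse(rowSums(labels == "ok") * 2L > ncol(labels), "ok", "no_ok"))
  }
  if (length(labels) %% 2L == 0L)
    stop("majority voting requires an odd number of votes")
  .checkBinary(labels, "vote")
  if (sum(labels == "ok") * 2L > length(labels)) "ok" else "no_ok"
}

#' Cross-tabulate two label sequences
#'
#' Entry (i, j) counts observations with \code{a == labels[i]} and
#' \code{b == labels[j]}; rows index the first sequence.
#'
#' @param a,b equal-length label vectors.
#' @param labels label order for rows/columns; defaults to the sorted union
#'   of observed values (use [binaryLevels()] for ok/no_ok tables).
#' @return square count matrix with dimnames.
#' @export
confusionCounts <- function(a, b, labels = NULL) {
  if (length(a) != length(b))
    stop(sprintf("label sequences differ in length (%d vs %d)",
                 length(a), length(b)))
  if (is.null(labels)) labels <- sort(unique(c(as.character(a), as.character(b))))
  fa <- factor(as.character(a), levels = as.character(labels))
  fb <- factor(as.character(b), levels = as.character(labels))
  if (anyNA(fa) || anyNA(fb))
    stop("observed values fall outside the declared label set")
  m <- table(fa, fb)
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(reference = labels, comparison = labels))
  m
}

#' Unweighted Cohen's kappa from a count matrix
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = \mathrm{trace}(m)/N} and chance agreement
#' \eqn{p_e = \sum_i r_i c_i / N^2} (row and column totals). When both
#' raters use a single category (\eqn{p_e = 1}), kappa is 1 if agreement is
#' perfect and undefined (an error) otherwise.
#'
#' @param m square non-negative count matrix with positive total.
#' @return kappa in \eqn{[-1, 1]}.
#' @export
cohenKappa <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("kappa needs a square count matrix")
  if (any(m < 0)) stop("kappa needs non-negative counts")
  total <- sum(m)
  if (total <= 0) stop("kappa is undefined for an empty count matrix")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    if (abs(po - 1) < 1e-12) return(1)
    stop("kappa undefined: chance agreement is 1 but observed agreement is not")
  }
  (po - pe) / (1 - pe)
}

#' Verbal interpretation of a kappa value
#'
#' Landis-Koch bands, with the top band called "Perfect": kappa below 0 is
#' Poor, [0, 0.20] Slight, (0.20, 0.40] Fair, (0.40, 0.60] Moderate,
#' (0.60, 0.80] Substantial and (0.80, 1] Perfect. Bands are closed on the
#' right.
#'
#' @param k numeric vector of kappa values in \eqn{[-1, 1]}.
#' @return character vector of categories.
#' @export
interpretKappa <- function(k) {
  if (any(is.na(k)) || any(k < -1 - 1e-12) || any(k > 1 + 1e-12))
    stop("kappa values must lie in [-1, 1]")
  vapply(k, function(x) {
    if (x < 0) "Poor"
    else if (x <= 0.20) "Slight"
    else if (x <= 0.40) "Fair"
    else if (x <= 0.60) "Moderate"
    else if (x <= 0.80) "Substantial"
    else "Perfect"
  }, character(1))
}

#' Group-size summary of a set of annotation triples
#'
#' @param triples n x 3 label matrix (or anything [assignGroup()] accepts).
#' @return named integer vector of counts for groups 1..4; sums to the
#'   number of triples.
#' @export
groupSizeSummary <- function(triples) {
  g <- assignGroup(triples)
  counts <- vapply(1:4, function(i) sum(g == i), integer(1))
  names(counts) <- as.character(1:4)
  counts
}

#' Fraction of frames with discordant expert annotations
#'
#' Discordant frames are those in groups 2 and 3 (at least one expert
#' disagreed with the others).
#'
#' @param counts named group-size vector as returned by
#'   [groupSizeSummary()], or a raw length-4 count vector ordered 1..4.
#' @return the fraction (counts of groups 2 and 3) / total.
#' @export
discordantFraction <- function(counts) {
  if (length(counts) != 4L) stop("expected counts for the four groups")
  counts <- as.numeric(counts)
  if (sum(counts) <= 0) stop("empty group counts")
  (counts[2] + counts[3]) / sum(counts)
}

#' Agreement between two annotators
#'
#' Builds the 2x2 ok/no_ok confusion matrix, computes unweighted Cohen's
#' kappa and its verbal category.
#'
#' @param a,b equal-length binary label vectors.
#' @param raters length-2 character naming the annotators.
#' @return an \linkS4class{AgreementReport}.
#' @export
agreementReport <- function(a, b, raters = c("rater1", "rater2")) {
  .checkBinary(a); .checkBinary(b)
  m <- confusionCounts(a, b, labels = BINARY_LEVELS)
  k <- cohenKappa(m)
  new("AgreementReport", confusion = m, kappa = k,
      category = interpretKappa(k), raters = as.character(raters))
}

#' Pairwise agreement between the three expert annotations
#'
#' @param annotations n x 3 label matrix (Expert 1..3).
#' @return list of three \linkS4class{AgreementReport} objects for the pairs
#'   (1,2), (1,3), (2,3). Experts 1 and 2 are the same person annotating a
#'   week apart, so that pair measures intra-observer agreement.
#' @export
pairwiseAgreement <- function(annotations) {
  m <- .asTripleMatrix(annotations)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  lapply(pairs, function(p)
    agreementReport(m[, p[1]], m[, p[2]],
                    raters = paste0("Expert", p)))
}

#' Export an agreement report as a CSV-ready data.frame
#'
#' @param report an \linkS4class{AgreementReport}.
#' @return data.frame with the flattened confusion matrix, kappa and category.
#' @export
agreementAsDataFrame <- function(report) {
  stopifnot(is(report, "AgreementReport"))
  m <- report@confusion
  data.frame(rater_a = report@raters[1], rater_b = report@raters[2],
             no_ok_no_ok = m[1, 1], no_ok_ok = m[1, 2],
             ok_no_ok = m[2, 1], ok_ok = m[2, 2],
             kappa = report@kappa, agreement = report@category,
             stringsAsFactors = FALSE)
}
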