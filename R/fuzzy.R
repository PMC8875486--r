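#' Construct a membership function
#'
#' @param kind \code{"triangular"} (3 breakpoints) or \code{"trapezoidal"}
#'   (4 breakpoints).
#' @param breakpoints non-decreasing numeric vector in \eqn{[0,1]}.
#' @return a \linkS4class{MembershipFunction}.
#' @examples
#' membershipFunction("triangular", c(0, 0.5, 1))
#' @export
membershipFunction <- function(kind, breakpoints) {
  new("MembershipFunction", kind = as.character(kind),
      breakpoints = as.numeric(breakpoints))
}

#' Membership degree of crisp values in a fuzzy set
#'
#' Piecewise-linear interpolation of the breakpoint shape. Coincident
#' breakpoints give vertical shoulders (e.g. a trapezoid with
#' \code{a == b} is fully on from its left edge).
#'
#' @param x numeric vector in \eqn{[0,1]}.
#' @param mf a \linkS4class{MembershipFunction}.
#' @return membership degrees in \eqn{[0,1]}, same length as \code{x}.
#' @export
fuzzify <- function(x, mf) {
  stopifnot(is(mf, "MembershipFunction"))
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop("fuzzify: values must lie in [0,1]")
  bp <- mf@breakpoints
  if (mf@kind == "triangular") {
    a <- bp[1]; b <- bp[2]; cc <- bp[2]; d <- bp[3]   # triangle = degenerate trapezoid
  } else {
    a <- bp[1]; b <- bp[2]; cc <- bp[3]; d <- bp[4]
  }
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  down <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= cc)
  deg <- pmin(up, 1, down)
  pmax(deg, 0)
}

#' Construct a Mamdani FIS specification
#'
#' @param inputSets named list of \linkS4class{MembershipFunction} shared by
#'   the three inputs.
#' @param outputSets named list of \linkS4class{MembershipFunction}.
#' @param rules data.frame with columns \code{in1,in2,in3,out} naming sets.
#' @return a \linkS4class{FisSpec}.
#' @export
fisSpec <- function(inputSets, outputSets, rules) {
  new("FisSpec", inputSets = inputSets, outputSets = outputSets,
      rules = as.data.frame(rules, stringsAsFactors = FALSE))
}

## The low/high supports overlap around the decision boundary (0.45-0.55) so
## that no score has zero membership in both sets; a dead zone at 0.5 would
## make the output fall back to the neutral value and break the monotone
## response in each input.
.defaultInputSets <- function() {
  list(low = membershipFunction("trapezoidal", c(0, 0, 0.2, 0.55)),
       high = membershipFunction("trapezoidal", c(0.45, 0.8, 1, 1)))
}

.defaultOutputSets <- function() {
  list(very_low = membershipFunction("triangular", c(0, 0.125, 0.25)),
       low = membershipFunction("triangular", c(0.25, 0.375, 0.5)),
       high = membershipFunction("triangular", c(0.5, 0.625, 0.75)),
       very_high = membershipFunction("triangular", c(0.75, 0.875, 1)))
}

.countHighRules <- function() {
  combos <- expand.grid(in1 = c("low", "high"), in2 = c("low", "high"),
                        in3 = c("low", "high"), stringsAsFactors = FALSE)
  nHigh <- rowSums(combos == "high")
  combos$out <- c("very_low", "low", "high", "very_high")[nHigh + 1L]
  combos
}

#' Default FIS specifications for the voting step
#'
#' Both defaults share the same symmetric rule base, keyed on the number of
#' "high" inputs among the three per-expert model scores (0 high maps to the
#' lowest output set, 3 high to the highest). With crisp 0/1 inputs the
#' thresholded binary decision then coincides with majority voting, and the
#' four-class bin mapping coincides with the group-label scheme.
#' \code{defaultBinaryFis()} is used for the binary path (path 4),
#' \code{defaultFourClassFis()} for the 4-group path (path 8).
#'
#' @return a \linkS4class{FisSpec}.
#' @export
defaultBinaryFis <- function() {
  fisSpec(.defaultInputSets(), .defaultOutputSets(), .countHighRules())
}

#' @rdname defaultBinaryFis
#' @export
defaultFourClassFis <- function() {
  fisSpec(.defaultInputSets(), .defaultOutputSets(), .countHighRules())
}

#' Evaluate the Mamdani FIS on score triples
#'
#' The full Mamdani pipeline: fuzzify each input against every declared
#' input set; each rule fires at the minimum of its three antecedent
#' degrees; the consequent set is clipped at the rule strength (minimum
#' implication); clipped sets are aggregated pointwise by maximum; the crisp
#' output is the centroid of the aggregated set, computed on a uniform grid
#' over \eqn{[0,1]}. If the aggregated set is identically zero the neutral
#' value 0.5 is returned.
#'
#' @param scores length-3 numeric vector in \eqn{[0,1]} (the three
#'   per-expert model ok-scores), or an n x 3 matrix of such triples.
#' @param spec a \linkS4class{FisSpec}.
#' @param gridN number of uniform grid points for defuzzification
#'   (default 1001).
#' @return numeric vector of crisp outputs in \eqn{[0,1]} (length n).
#' @export
fisOutput <- function(scores, spec = defaultBinaryFis(), gridN = 1001L) {
  stopifnot(is(spec, "FisSpec"))
  validObject(spec)
  if (!is.matrix(scores)) {
    if (length(scores) != 3L) stop("a score triple must have length 3")
    scores <- matrix(scores, nrow = 1L)
  }
  if (ncol(scores) != 3L) stop("score matrix must have 3 columns")
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1))
    stop("FIS input scores must lie in [0,1]")
  n <- nrow(scores)
  inNames <- names(spec@inputSets)
  outNames <- names(spec@outputSets)

  # degrees[[set]] is an n x 3 matrix of membership degrees
  degrees <- lapply(spec@inputSets, function(mf) {
    matrix(fuzzify(as.vector(scores), mf), nrow = n)
  })

  # rule strengths: n x nRules
  r <- spec@rules
  strength <- vapply(seq_len(nrow(r)), function(j) {
    pmin(degrees[[r$in1[j]]][, 1], degrees[[r$in2[j]]][, 2],
         degrees[[r$in3[j]]][, 3])
  }, numeric(n))
  strength <- matrix(strength, nrow = n)

  # per output set, clip level = max strength over rules with that consequent
  clip <- vapply(outNames, function(s) {
    cols <- which(r$out == s)
    if (length(cols) == 0L) return(rep(0, n))
    apply(strength[, cols, drop = FALSE], 1L, max)
  }, numeric(n))
  clip <- matrix(clip, nrow = n, dimnames = list(NULL, outNames))

  grid <- seq(0, 1, length.out = as.integer(gridN))
  mus <- vapply(spec@outputSets, function(mf) fuzzify(grid, mf), numeric(length(grid)))

  # aggregated membership per frame: max over sets of min(clip, mu(grid)).
  # Built as grid x n matrices, set by set, to stay vectorized.
  agg <- matrix(0, nrow = length(grid), ncol = n)
  for (s in seq_along(outNames)) {
    clipped <- pmin(matrix(mus[, s], nrow = length(grid), ncol = n),
                    matrix(clip[, s], nrow = length(grid), ncol = n, byrow = TRUE))
    agg <- pmax(agg, clipped)
  }
  mass <- colSums(agg)
  out <- ifelse(mass > 0, colSums(agg * grid) / mass, 0.5)
  unname(out)
}

#' Binary decision from a FIS output
#'
#' The class boundary is 0.5; outputs at exactly 0.5 are assigned upward to
#' \code{"ok"}. The 0.25/0.75 thresholds of the uniform thresholding scheme
#' act as confidence bounds (see [confidenceFromOutput()] and
#' [mapOutputToGroup()]).
#'
#' @param y numeric vector in \eqn{[0,1]}.
#' @return character vector of binary labels.
#' @export
thresholdBinary <- function(y) {
  if (any(is.na(y)) || any(y < 0) || any(y > 1))
    stop("FIS outputs must lie in [0,1]")
  ifelse(y >= 0.5, "ok", "no_ok")
}

#' Map a FIS output to a four-group label by uniform thresholding
#'
#' Bins: output below 0.25 gives group 1, [0.25, 0.5) group 3, [0.5, 0.75]
#' group 2 and above 0.75 group 4. The boundary 0.5 goes to the ok-side
#' group 2, consistent with the upward tie rule of [thresholdBinary()], so
#' groups \{2, 4\} always collapse to ok and \{1, 3\} to no_ok.
#'
#' @param y numeric vector in \eqn{[0,1]}.
#' @return integer vector of group labels 1..4.
#' @export
mapOutputToGroup <- function(y) {
  if (any(is.na(y)) || any(y < 0) || any(y > 1))
    stop("FIS outputs must lie in [0,1]")
  ifelse(y < 0.25, 1L, ifelse(y < 0.5, 3L, ifelse(y <= 0.75, 2L, 4L)))
}

#' Confidence measure derived from a FIS output
#'
#' Twice the distance of the output from the decision boundary:
#' \eqn{2 |y - 0.5|}. Frames classified as definitely correct (or definitely
#' incorrect) score 1; frames at the boundary score 0.
#'
#' @param y numeric vector in \eqn{[0,1]}.
#' @return confidences in \eqn{[0,1]}.
#' @export
confidenceFromOutput <- function(y) {
  if (any(is.na(y)) || any(y < 0) || any(y > 1))
    stop("FIS outputs must lie in [0,1]")
  2 * abs(y - 0.5)
}

#' Per-group histograms of FIS outputs
#'
#' @param outputs numeric vector of FIS outputs in \eqn{[0,1]}.
#' @param groups parallel vector of group labels 1..4.
#' @param bins number of equal-width bins over \eqn{[0,1]}.
#' @return 4 x bins integer matrix of counts; row g sums to the size of
#'   group g.
#' @export
outputHistogram <- function(outputs, groups, bins = 20L) {
  if (length(outputs) != length(groups))
    stop("outputs and groups differ in length")
  if (any(outputs < 0) || any(outputs > 1)) stop("outputs must lie in [0,1]")
  if (!all(groups %in% 1:4)) stop("groups must be in 1..4")
  breaks <- seq(0, 1, length.out = bins + 1L)
  binOf <- pmin(pmax(findInterval(outputs, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, nrow = 4L, ncol = bins,
                   dimnames = list(group = 1:4, bin = seq_len(bins)))
  for (g in 1:4) {
    tab <- tabulate(binOf[groups == g], nbins = bins)
    counts[g, ] <- as.integer(tab)
  }
  counts
}

#' Read / write a FIS specification as YAML
#'
#' The on-disk format declares the named input and output sets (kind and
#' breakpoints) and the rule list. Two defaults ship with the package under
#' \code{inst/extdata} (\code{fis_binary.yaml}, \code{fis_fourclass.yaml}).
#'
#' @param path file path.
#' @return [readFisSpec()] returns a \linkS4class{FisSpec};
#'   [writeFisSpec()] returns \code{path} invisibly.
#' @export
readFisSpec <- function(path) {
  raw <- yaml::read_yaml(path)
  parseSets <- function(lst) {
    out <- lapply(lst, function(s)
      membershipFunction(s$kind, as.numeric(s$breakpoints)))
    names(out) <- names(lst)
    out
  }
  rules <- do.call(rbind, lapply(raw$rules, function(r)
    data.frame(in1 = r$`if`[[1]], in2 = r$`if`[[2]], in3 = r$`if`[[3]],
               out = r$then, stringsAsFactors = FALSE)))
  fisSpec(parseSets(raw$input_sets), parseSets(raw$output_sets), rules)
}

#' @rdname readFisSpec
#' @param spec a \linkS4class{FisSpec}.
#' @export
writeFisSpec <- function(spec, path) {
  stopifnot(is(spec, "FisSpec"))
  dumpSets <- function(sets) lapply(sets, function(mf)
    list(kind = mf@kind, breakpoints = as.numeric(mf@breakpoints)))
  r <- spec@rules
  rules <- lapply(seq_len(nrow(r)), function(i)
    list(`if` = c(r$in1[i], r$in2[i], r$in3[i]), then = r$out[i]))
  yaml::write_yaml(list(input_sets = dumpSets(spec@inputSets),
                        output_sets = dumpSets(spec@outputSets),
                        rules = rules), path)
  invisible(path)
}
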