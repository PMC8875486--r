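# Shared fixture builders. Everything is generated in code at test time.

allTripleCombos <- function() {
  as.matrix(expand.grid(e1 = c("ok", "no_ok"), e2 = c("ok", "no_ok"),
                        e3 = c("ok", "no_ok"), stringsAsFactors = FALSE))
}

# Independent kappa evaluation, written directly from the definition and
# kept separate from the package implementation.
referenceKappa <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  r <- rowSums(m); cl <- colSums(m)
  pe <- sum(r * cl) / n^2
  (po - pe) / (1 - pe)
}

# Independent Mamdani evaluation on a fine grid, using stats::approx for the
# membership shapes instead of the package's fuzzify().
referenceFisOutput <- function(scores, spec, nGrid = 1e5) {
  mfFun <- function(mf) {
    bp <- mf@breakpoints
    if (mf@kind == "triangular") {
      xs <- c(bp[1], bp[2], bp[3]); ys <- c(0, 1, 0)
    } else {
      xs <- c(bp[1], bp[2], bp[3], bp[4]); ys <- c(0, 1, 1, 0)
    }
    # guard collapsed shoulders: evaluate just inside
    function(x) {
      out <- numeric(length(x))
      for (i in seq_along(x)) {
        xi <- x[i]
        if (xi < xs[1] || xi > xs[length(xs)]) { out[i] <- 0; next }
        seg <- findInterval(xi, xs, all.inside = TRUE)
        x0 <- xs[seg]; x1 <- xs[seg + 1]
        y0 <- ys[seg]; y1 <- ys[seg + 1]
        out[i] <- if (x1 == x0) max(y0, y1) else y0 + (y1 - y0) * (xi - x0) / (x1 - x0)
      }
      out
    }
  }
  inFuns <- lapply(spec@inputSets, mfFun)
  outFuns <- lapply(spec@outputSets, mfFun)
  r <- spec@rules
  strength <- sapply(seq_len(nrow(r)), function(j) {
    min(inFuns[[r$in1[j]]](scores[1]), inFuns[[r$in2[j]]](scores[2]),
        inFuns[[r$in3[j]]](scores[3]))
  })
  grid <- seq(0, 1, length.out = nGrid)
  agg <- rep(0, nGrid)
  for (s in names(spec@outputSets)) {
    lev <- max(c(0, strength[r$out == s]))
    if (lev > 0) agg <- pmax(agg, pmin(lev, outFuns[[s]](grid)))
  }
  if (sum(agg) == 0) return(0.5)
  sum(agg * grid) / sum(agg)
}

# Random valid FIS specification (2 input sets, 3 output sets, full rule
# base with random consequents).
randomFisSpec <- function() {
  sortedBp <- function(k) sort(round(runif(k), 3))
  inputSets <- list(low = membershipFunction("trapezoidal", sortedBp(4)),
                    high = membershipFunction("trapezoidal", sortedBp(4)))
  outputSets <- list(o1 = membershipFunction("triangular", sortedBp(3)),
                     o2 = membershipFunction("trapezoidal", sortedBp(4)),
                     o3 = membershipFunction("triangular", sortedBp(3)))
  combos <- expand.grid(in1 = names(inputSets), in2 = names(inputSets),
                        in3 = names(inputSets), stringsAsFactors = FALSE)
  combos$out <- sample(names(outputSets), nrow(combos), replace = TRUE)
  fisSpec(inputSets, outputSets, combos)
}

# A tiny in-memory dataset with unanimous, separable annotations.
tinyUnanimousDataset <- function(n = 24, seed = 5) {
  set.seed(seed)
  stopifnot(n %% 2 == 0)
  cls <- c(rep("correct", n / 2),
           sample(c("no_contact", "low_contrast", "geometry_artifact", "shadow"),
                  n / 2, replace = TRUE))
  pix <- lapply(cls, function(cl) generateFrame(cl)$pixels)
  lab <- rep(c("ok", "no_ok"), each = n / 2)
  info <- data.frame(file_name = sprintf("p%02d_loc1_%04d.png", seq_len(n), seq_len(n)),
                     patient_id = sprintf("%02d", seq_len(n)),
                     facial_location = "loc1",
                     image_id = sprintf("%04d", seq_len(n)),
                     session_id = "01012030", stringsAsFactors = FALSE)
  hfusDataset(info, cbind(lab, lab, lab), pix)
}
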