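#' Tally amino acids by window position
#'
#' Builds the 20 x L matrix X[i, j] counting occurrences of amino acid i at
#' position j over a window set. The padding letter "X" contributes to no
#' row, so the per-position effective count equals the number of non-padded
#' windows at that position.
#'
#' @param windows a [PeptideWindowSet-class] or character vector of window
#'   strings of one fixed length.
#' @return a [PositionCounts-class].
#' @examples
#' countPositions(c("ACA", "CCC"))
#' @export
countPositions <- function(windows) {
  res <- if (is(windows, "PeptideWindowSet")) windows@residues else
    as.character(windows)
  if (length(res) == 0L) stop("cannot tally an empty window set")
  mat <- residueMatrix(res)
  L <- ncol(mat)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(mat[, j], AA20), nbins = 20L)
  }, integer(20L))
  dimnames(counts) <- list(AA20, NULL)
  new("PositionCounts", counts = counts, n = nrow(mat),
      effectiveN = as.integer(colSums(counts)))
}

#' Relative position-specific propensities
#'
#' For each amino acid x and position j, the ratio of its positional
#' frequency in the positive (S-nitrosylated) window set over its frequency
#' in the negative set; r > 1 means enrichment around modified cysteines.
#' Frequencies are (X + pseudocount) / (effectiveN + 20 * pseudocount). With
#' pseudocount 0, cells whose negative-set frequency is zero (or whose
#' position has no observations in either set) are undefined (NA) and
#' excluded from the per-residue averages; so is the center column, which is
#' constitutively "C" in both classes.
#'
#' @param posCounts,negCounts [PositionCounts-class] for the two classes,
#'   same L.
#' @param pseudocount non-negative smoothing constant (default 0).
#' @return a [PropensityMatrix-class].
#' @export
relativePropensity <- function(posCounts, negCounts, pseudocount = 0) {
  stopifnot(is(posCounts, "PositionCounts"), is(negCounts, "PositionCounts"))
  if (ncol(posCounts@counts) != ncol(negCounts@counts)) {
    stop("positive and negative counts cover different window lengths")
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  L <- ncol(posCounts@counts)
  fPos <- sweep(posCounts@counts + pseudocount, 2,
                posCounts@effectiveN + 20 * pseudocount, "/")
  fNeg <- sweep(negCounts@counts + pseudocount, 2,
                negCounts@effectiveN + 20 * pseudocount, "/")
  r <- fPos / fNeg
  r[!is.finite(r)] <- NA_real_
  dimnames(r) <- list(AA20, NULL)
  use <- r
  use[, (L + 1L) / 2L] <- NA_real_  # center column excluded from averages
  avg <- rowMeans(use, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  new("PropensityMatrix", r = r, averages = avg, pseudocount = pseudocount)
}

#' Raw bi-profile Bayes positional posteriors
#'
#' Positional frequency estimate of the posterior probability of each amino
#' acid at each position: entry(i, j) = X[i, j] / effectiveN[j]. Positions
#' with no non-"X" observations yield an all-zero column.
#'
#' @param counts a [PositionCounts-class].
#' @return 20 x L numeric matrix.
#' @export
bpbPosterior <- function(counts) {
  stopifnot(is(counts, "PositionCounts"))
  if (counts@n < 1L) stop("at least one window required")
  denom <- ifelse(counts@effectiveN == 0L, 1L, counts@effectiveN)
  out <- sweep(counts@counts, 2, denom, "/")
  out[, counts@effectiveN == 0L] <- 0
  out
}

#' Standard normal cumulative distribution function
#'
#' Thin validated wrapper used by the ANBPB posterior; exact to well below
#' 1e-10 absolute error.
#'
#' @param x numeric vector of finite values.
#' @return Phi(x), elementwise.
#' @examples
#' normalCdf(0)    # 0.5
#' normalCdf(1)    # 0.8413447
#' @export
normalCdf <- function(x) {
  if (any(!is.finite(x))) stop("normalCdf requires finite input")
  pnorm(x)
}

#' Adapted normal-distribution positional posteriors (ANBPB)
#'
#' Each positional count X[i, j] is treated as a draw from the binomial
#' b(n, p) with n windows and background probability p = 1/20, so its
#' expectation is n * p. To emphasize between-residue contrast at a
#' position, the count is standardized not by the binomial spread but by
#' V[j], the population standard deviation (divisor 20) of the twenty
#' counts observed at position j, and mapped through the standard normal
#' CDF:
#'   entry(i, j) = Phi((X[i, j] - n * p) / V[j]).
#' A degenerate position with V[j] = 0 (all twenty counts equal) yields the
#' neutral value Phi(0) = 0.5. The standardization mean uses the nominal n
#' even at padded positions where the effective count is smaller.
#'
#' @param counts a [PositionCounts-class] built from at least 2 windows.
#' @param p background per-residue probability (default 1/20).
#' @return 20 x L numeric matrix with entries in (0, 1).
#' @export
anbpbPosterior <- function(counts, p = 1 / 20) {
  stopifnot(is(counts, "PositionCounts"))
  if (counts@n < 2L) stop("ANBPB standardization requires at least 2 windows")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  X <- counts@counts
  colMean <- colMeans(X)
  V <- sqrt(colMeans(sweep(X, 2, colMean, "-")^2))  # population sd, divisor 20
  Z <- sweep(X, 2, counts@n * p, "-")
  out <- matrix(0.5, nrow = 20L, ncol = ncol(X), dimnames = list(AA20, NULL))
  ok <- V > 0
  if (any(ok)) {
    out[, ok] <- pnorm(sweep(Z[, ok, drop = FALSE], 2, V[ok], "/"))
  }
  out
}

#' Build a bi-profile from labeled windows
#'
#' Computes the positive and negative posterior matrices with
#' [bpbPosterior()] or [anbpbPosterior()] on the per-class position counts.
#'
#' @param posWindows,negWindows [PeptideWindowSet-class] or character
#'   vectors of windows for each class; both non-empty, same length L.
#' @param method "anbpb" (default) or "bpb".
#' @param p background per-residue probability for ANBPB.
#' @return a [BiProfile-class].
#' @export
buildBiProfile <- function(posWindows, negWindows,
                           method = c("anbpb", "bpb"), p = 1 / 20) {
  method <- match.arg(method)
  cPos <- countPositions(posWindows)
  cNeg <- countPositions(negWindows)
  if (ncol(cPos@counts) != ncol(cNeg@counts)) {
    stop("positive and negative windows have different lengths")
  }
  post <- switch(method,
                 bpb = list(bpbPosterior(cPos), bpbPosterior(cNeg)),
                 anbpb = list(anbpbPosterior(cPos, p), anbpbPosterior(cNeg, p)))
  new("BiProfile", method = method, pos = post[[1]], neg = post[[2]],
      nPos = cPos@n, nNeg = cNeg@n, p = p)
}

biProfileFromCounts <- function(cPos, cNeg, method, p = 1 / 20) {
  post <- switch(method,
                 bpb = list(bpbPosterior(cPos), bpbPosterior(cNeg)),
                 anbpb = list(anbpbPosterior(cPos, p), anbpbPosterior(cNeg, p)))
  new("BiProfile", method = method, pos = post[[1]], neg = post[[2]],
      nPos = cPos@n, nNeg = cNeg@n, p = p)
}

#' Serialize / deserialize a BiProfile as JSON
#'
#' Profiles are written as a self-describing JSON document (method,
#' class sizes, background p, row/column labels and both matrices) so that
#' trained profiles are portable and diffable.
#'
#' @param profile a [BiProfile-class].
#' @param path file path.
#' @return \code{readBiProfile}: a [BiProfile-class]; \code{writeBiProfile}:
#'   invisibly, \code{path}.
#' @export
writeBiProfile <- function(profile, path) {
  doc <- list(
    format = "snoANBPB-biprofile", version = "1",
    method = profile@method, nPos = profile@nPos, nNeg = profile@nNeg,
    p = profile@p, rows = AA20, L = ncol(profile@pos),
    pos = unname(profile@pos), neg = unname(profile@neg))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBiProfile
#' @export
readBiProfile <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "snoANBPB-biprofile")) {
    stop("not a bi-profile document: ", path)
  }
  asProfileMatrix <- function(m) {
    m <- matrix(as.numeric(m), nrow = 20L)
    dimnames(m) <- list(AA20, NULL)
    m
  }
  pos <- asProfileMatrix(doc$pos)
  neg <- asProfileMatrix(doc$neg)
  new("BiProfile", method = doc$method, pos = pos, neg = neg,
      nPos = as.integer(doc$nPos), nNeg = as.integer(doc$nNeg),
      p = as.numeric(doc$p))
}
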