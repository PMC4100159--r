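#' Pseudo-amino-acid composition features
#'
#' Fractions of a window's non-padding residues falling in the two fixed
#' physicochemical classes: the "positively charged" partition
#' \{A, C, D, E, H, L, P, Q, S, V, W\} and the alpha-helix-propensity
#' partition \{C, D, G, N, P, S, T, W, Y\}. The complementary classes are
#' linearly dependent on these, so only these two fractions are emitted.
#' Padding "X" is excluded from the denominator (it is not an amino acid).
#'
#' @param window a window string or a [PeptideWindowSet-class] (vectorized
#'   over windows).
#' @return a numeric matrix with columns \code{fA} and \code{fH}, one row
#'   per window (a 1-row matrix for a single string).
#' @examples
#' compositionFeatures("GGGGGGGGGGCGGGGGGGGGG")  # fA = 1/21, fH = 1
#' @export
compositionFeatures <- function(window) {
  res <- if (is(window, "PeptideWindowSet")) window@residues else
    as.character(window)
  mat <- residueMatrix(res)
  nonX <- rowSums(mat != PAD)
  if (any(nonX == 0L)) stop("all-'X' window: composition undefined")
  fA <- rowSums(matrix(mat %in% CLASS_A, nrow = nrow(mat))) / nonX
  fH <- rowSums(matrix(mat %in% CLASS_H, nrow = nrow(mat))) / nonX
  cbind(fA = fA, fH = fH)
}

neutralPosterior <- function(method) if (method == "anbpb") 0.5 else 1 / 20

#' Encode windows as bi-profile + composition feature vectors
#'
#' Each window of length L maps to a vector of 2 * (L - 1) + 2 features
#' (42 at the default L = 21): the positive-profile posterior of the
#' window's residue at each of the L - 1 flanking positions left to right
#' (the center is excluded: it is constitutively cysteine in both classes
#' and carries no signal), then the same from the negative profile, then
#' the two composition fractions. A padding "X" residue looks up the
#' neutral posterior (0.5 for ANBPB, 1/20 for BPB) so that terminal padding
#' never masquerades as class evidence.
#'
#' @param windows a [PeptideWindowSet-class] or character vector of window
#'   strings whose length matches the profile's L.
#' @param profile a [BiProfile-class].
#' @return numeric matrix, one row per window, columns psi1..psi42 (for
#'   L = 21); attribute \code{layout} records method, L, feature count and
#'   center exclusion. Zero windows yield a 0-row matrix.
#' @export
encodeDataset <- function(windows, profile) {
  stopifnot(is(profile, "BiProfile"))
  res <- if (is(windows, "PeptideWindowSet")) windows@residues else
    as.character(windows)
  L <- ncol(profile@pos)
  layout <- list(method = profile@method, L = L,
                 nFeatures = 2L * (L - 1L) + 2L, centerExcluded = TRUE)
  if (length(res) == 0L) {
    out <- matrix(numeric(0), nrow = 0L, ncol = layout$nFeatures,
                  dimnames = list(NULL, paste0("psi", seq_len(layout$nFeatures))))
    attr(out, "layout") <- layout
    return(out)
  }
  mat <- residueMatrix(res)
  if (ncol(mat) != L) {
    stop("window length ", ncol(mat), " does not match profile L = ", L)
  }
  center <- (L + 1L) / 2L
  flanks <- setdiff(seq_len(L), center)
  aaIdx <- matrix(match(mat[, flanks, drop = FALSE], AA20), nrow = nrow(mat))
  posIdx <- matrix(rep(flanks, each = nrow(mat)), nrow = nrow(mat))
  neutral <- neutralPosterior(profile@method)
  lookup <- function(prof) {
    v <- prof[cbind(as.vector(aaIdx), as.vector(posIdx))]
    v[is.na(v)] <- neutral  # "X" residues
    matrix(v, nrow = nrow(mat))
  }
  out <- cbind(lookup(profile@pos), lookup(profile@neg),
               compositionFeatures(res))
  dimnames(out) <- list(NULL, paste0("psi", seq_len(ncol(out))))
  attr(out, "layout") <- layout
  out
}

#' @rdname encodeDataset
#' @param window a single window string.
#' @return \code{encodeWindow}: a named numeric vector of length
#'   2 * (L - 1) + 2.
#' @export
encodeWindow <- function(window, profile) {
  stopifnot(length(window) == 1L)
  encodeDataset(window, profile)[1L, ]
}

#' Write an encoded feature matrix as TSV
#'
#' One row per window: the psi features followed by a \code{label} column.
#'
#' @param features matrix from [encodeDataset()].
#' @param labels +1/-1 vector, one per row.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFeatures <- function(features, labels, path) {
  stopifnot(nrow(features) == length(labels))
  tab <- data.frame(features, label = as.integer(labels), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
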