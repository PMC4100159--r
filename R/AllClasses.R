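#' PeptideWindowSet: labeled fixed-length cysteine-centered windows
#'
#' Container for a set of peptide windows of one fixed odd length L over the
#' 21-letter alphabet (20 amino acids plus the terminal-padding letter "X"),
#' each carrying a class label (+1 S-nitrosylated, -1 not) and, optionally,
#' the protein id and 1-based site position it was extracted from.
#'
#' Validity requires: equal slot lengths; a single odd window length; all
#' letters in the window alphabet; "X" only as a contiguous prefix and/or
#' suffix; a non-"X" central residue; labels in \{-1, +1\}. The central
#' residue is "C" for every window produced by [extractDataset()] under
#' default settings.
#'
#' @slot residues character vector of window strings, all of length L.
#' @slot label integer vector of +1/-1 class labels.
#' @slot proteinId character vector of source protein ids (NA if unknown).
#' @slot position integer vector of 1-based site positions (NA if unknown).
#'
#' @aliases PeptideWindowSet-class
#' @export PeptideWindowSet
#' @exportClass PeptideWindowSet
PeptideWindowSet <- setClass("PeptideWindowSet",
  slots = c(residues = "character", label = "integer",
            proteinId = "character", position = "integer"))

setValidity("PeptideWindowSet", function(object) {
  n <- length(object@residues)
  if (length(object@label) != n || length(object@proteinId) != n ||
      length(object@position) != n) {
    return("slot lengths differ")
  }
  if (n == 0L) return(TRUE)
  L <- unique(nchar(object@residues))
  if (length(L) != 1L) return("windows have mixed lengths")
  if (L %% 2L != 1L) return("window length must be odd")
  if (!all(object@label %in% c(-1L, 1L))) return("labels must be +1 or -1")
  mat <- residueMatrix(object@residues)
  if (!all(mat %in% WINDOW_ALPHABET)) {
    return("residues outside the 20-amino-acid + 'X' alphabet")
  }
  center <- (L + 1L) / 2L
  if (any(mat[, center] == PAD)) return("central residue must not be 'X'")
  ## "X" must form a contiguous terminal prefix/suffix
  for (i in seq_len(n)) {
    xs <- which(mat[i, ] == PAD)
    if (length(xs) == 0L) next
    pre <- xs[xs < center]
    suf <- xs[xs > center]
    if (!identical(pre, seq_len(length(pre))) ||
        !identical(suf, seq.int(L - length(suf) + 1L, length.out = length(suf)))) {
      return(sprintf("window %d: 'X' not a contiguous terminal pad", i))
    }
  }
  TRUE
})

#' Construct a PeptideWindowSet
#'
#' @param residues character vector of window strings (one fixed odd length).
#' @param label numeric/integer vector of +1/-1 labels.
#' @param proteinId,position optional provenance vectors.
#' @return A [PeptideWindowSet-class] object.
#' @examples
#' peptideWindowSet(c("AACAA", "DDCDD"), c(1, -1))
#' @export
peptideWindowSet <- function(residues, label,
                             proteinId = rep(NA_character_, length(residues)),
                             position = rep(NA_integer_, length(residues))) {
  new("PeptideWindowSet", residues = as.character(residues),
      label = as.integer(label), proteinId = as.character(proteinId),
      position = as.integer(position))
}

#' @describeIn PeptideWindowSet-class number of windows
#' @param x,object a \code{PeptideWindowSet}
#' @export
setMethod("length", "PeptideWindowSet", function(x) length(x@residues))

#' @describeIn PeptideWindowSet-class subset windows
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "PeptideWindowSet", function(x, i, j, ..., drop = TRUE) {
  peptideWindowSet(x@residues[i], x@label[i], x@proteinId[i], x@position[i])
})

setMethod("show", "PeptideWindowSet", function(object) {
  n <- length(object)
  L <- if (n) nchar(object@residues[1]) else NA_integer_
  cat(sprintf("PeptideWindowSet: %d windows (L = %s), %d positive / %d negative\n",
              n, L, sum(object@label == 1L), sum(object@label == -1L)))
  if (n) {
    k <- min(n, 3L)
    for (i in seq_len(k)) {
      cat(sprintf("  %s  %+d\n", object@residues[i], object@label[i]))
    }
    if (n > k) cat("  ...\n")
  }
})

#' @rdname peptideWindowSet
#' @param x a \code{PeptideWindowSet}
#' @export
residues <- function(x) x@residues

#' @rdname peptideWindowSet
#' @export
siteLabels <- function(x) x@label

#' @rdname peptideWindowSet
#' @export
windowLength <- function(x) {
  if (length(x) == 0L) NA_integer_ else nchar(x@residues[1])
}

#' PositionCounts: amino-acid-by-position count matrix
#'
#' Tally X[i, j] of amino acid i (rows, the 20 standard residues in fixed
#' order) at window position j (columns, 1..L) over a window set. Padding
#' "X" contributes to no row, so the per-position effective count
#' (column sum) can be smaller than the number of windows n.
#'
#' @slot counts 20 x L integer matrix, rownames the amino acids.
#' @slot n integer, number of windows tallied.
#' @slot effectiveN integer vector of per-position non-"X" counts.
#' @aliases PositionCounts-class
#' @export PositionCounts
#' @exportClass PositionCounts
PositionCounts <- setClass("PositionCounts",
  slots = c(counts = "matrix", n = "integer", effectiveN = "integer"))

setValidity("PositionCounts", function(object) {
  if (nrow(object@counts) != 20L) return("counts must have 20 rows")
  if (!identical(rownames(object@counts), AA20)) {
    return("rownames must be the 20 amino acids in fixed order")
  }
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (length(object@effectiveN) != ncol(object@counts)) {
    return("effectiveN length must equal the number of positions")
  }
  if (!all(colSums(object@counts) == object@effectiveN)) {
    return("column sums must equal effectiveN")
  }
  if (any(object@effectiveN > object@n)) return("effectiveN must not exceed n")
  TRUE
})

setMethod("show", "PositionCounts", function(object) {
  cat(sprintf("PositionCounts: %d windows x %d positions (min effective n = %d)\n",
              object@n, ncol(object@counts), min(object@effectiveN)))
})

#' BiProfile: paired positive/negative position-specific posteriors
#'
#' The positive and negative 20 x L posterior matrices of a bi-profile Bayes
#' encoding, either raw positional frequencies (method "bpb") or
#' normal-standardized scores mapped through the standard normal CDF
#' (method "anbpb").
#'
#' @slot method "bpb" or "anbpb".
#' @slot pos,neg 20 x L numeric matrices with entries in [0, 1].
#' @slot nPos,nNeg integer class sizes the profiles were built from.
#' @slot p numeric, the background per-residue probability (1/20).
#' @aliases BiProfile-class
#' @export BiProfile
#' @exportClass BiProfile
BiProfile <- setClass("BiProfile",
  slots = c(method = "character", pos = "matrix", neg = "matrix",
            nPos = "integer", nNeg = "integer", p = "numeric"))

setValidity("BiProfile", function(object) {
  if (!object@method %in% c("bpb", "anbpb")) return("unknown profile method")
  if (!identical(dim(object@pos), dim(object@neg))) {
    return("pos and neg matrices must have identical dimensions")
  }
  if (nrow(object@pos) != 20L) return("profile matrices must have 20 rows")
  rng <- range(object@pos, object@neg)
  if (rng[1] < 0 || rng[2] > 1) return("posterior entries must lie in [0, 1]")
  if (object@p <= 0 || object@p >= 1) return("p must lie in (0, 1)")
  TRUE
})

setMethod("show", "BiProfile", function(object) {
  cat(sprintf("BiProfile (%s): L = %d, built from %d positive / %d negative windows, p = %.4g\n",
              object@method, ncol(object@pos), object@nPos, object@nNeg,
              object@p))
})

#' @rdname buildBiProfile
#' @param x a \code{BiProfile}
#' @export
profileMethod <- function(x) x@method

#' @rdname buildBiProfile
#' @export
positiveProfile <- function(x) x@pos

#' @rdname buildBiProfile
#' @export
negativeProfile <- function(x) x@neg

#' PropensityMatrix: relative position-specific amino-acid propensities
#'
#' Ratios r[x, j] of the frequency of amino acid x at position j in the
#' positive window set over its frequency in the negative set; values > 1
#' indicate enrichment around S-nitrosylated cysteines. Entries whose
#' negative-set frequency is zero (at pseudocount 0) are undefined (NA) and
#' excluded from the per-residue averages, as is the invariant center column.
#'
#' @slot r 20 x L numeric matrix of ratios (NA where undefined).
#' @slot averages named length-20 vector of per-residue means over defined,
#'   non-center positions.
#' @slot pseudocount the pseudocount used.
#' @aliases PropensityMatrix-class
#' @export PropensityMatrix
#' @exportClass PropensityMatrix
PropensityMatrix <- setClass("PropensityMatrix",
  slots = c(r = "matrix", averages = "numeric", pseudocount = "numeric"))

setValidity("PropensityMatrix", function(object) {
  if (nrow(object@r) != 20L) return("r must have 20 rows")
  if (any(object@r < 0, na.rm = TRUE)) return("ratios must be non-negative")
  if (length(object@averages) != 20L) return("averages must have length 20")
  TRUE
})

setMethod("show", "PropensityMatrix", function(object) {
  avg <- sort(object@averages, decreasing = TRUE)
  cat(sprintf("PropensityMatrix: %d positions, pseudocount %.3g\n",
              ncol(object@r), object@pseudocount))
  cat("  most enriched: ",
      paste(sprintf("%s=%.2f", names(avg)[1:3], avg[1:3]), collapse = ", "),
      "\n  most depleted: ",
      paste(sprintf("%s=%.2f", rev(names(avg))[1:3], rev(avg)[1:3]),
            collapse = ", "), "\n", sep = "")
})

#' ModelConfig: classifier hyper-parameters
#'
#' Configuration of the class-weighted soft-margin RBF-kernel SVM. The
#' misclassification penalty is cost * wPos for the positive class and
#' cost * wNeg for the negative class. Defaults are the published operating
#' point: cost 22.6274 (2^4.5), gamma 0.03125 (2^-5), wPos 2, wNeg 1.
#'
#' @slot cost positive soft-margin penalty C.
#' @slot gamma positive RBF kernel width parameter.
#' @slot wPos,wNeg positive class-weight multipliers.
#' @slot kernel kernel name; only "rbf" is supported.
#' @slot tolerance optimizer termination tolerance, recorded for
#'   reproducibility.
#' @aliases ModelConfig-class
#' @export ModelConfig
#' @exportClass ModelConfig
ModelConfig <- setClass("ModelConfig",
  slots = c(cost = "numeric", gamma = "numeric", wPos = "numeric",
            wNeg = "numeric", kernel = "character", tolerance = "numeric"))

setValidity("ModelConfig", function(object) {
  if (object@cost <= 0 || object@gamma <= 0 || object@wPos <= 0 ||
      object@wNeg <= 0 || object@tolerance <= 0) {
    return("cost, gamma, class weights and tolerance must be strictly positive")
  }
  if (!identical(object@kernel, "rbf")) return("only the 'rbf' kernel is supported")
  TRUE
})

#' @rdname ModelConfig-class
#' @param cost,gamma,wPos,wNeg,tolerance see slots.
#' @return a \code{ModelConfig}
#' @examples
#' modelConfig()                 # the published operating point
#' modelConfig(wPos = 1.5)
#' @export
modelConfig <- function(cost = 22.6274, gamma = 0.03125, wPos = 2,
                        wNeg = 1, tolerance = 1e-6) {
  new("ModelConfig", cost = cost, gamma = gamma, wPos = wPos, wNeg = wNeg,
      kernel = "rbf", tolerance = tolerance)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: rbf kernel, C = %g, gamma = %g, weights +1:%g / -1:%g\n",
              object@cost, object@gamma, object@wPos, object@wNeg))
})

#' SnoModel: a trained S-nitrosylation site classifier
#'
#' Bundles the classifier configuration, the bi-profile used for encoding,
#' the feature layout, and the fitted decision function (support vectors,
#' coefficients, offset). Predictions are computed directly from this state,
#' so a model serialized with [writeModel()] and reloaded predicts
#' identically.
#'
#' @slot config a [ModelConfig-class].
#' @slot profile the [BiProfile-class] used to encode windows.
#' @slot sv numeric matrix of support vectors (rows).
#' @slot coefs numeric vector of dual coefficients (one per support vector).
#' @slot rho numeric decision-function offset.
#' @slot flip +1 or -1, orienting the decision value so that positive means
#'   the +1 class.
#' @slot layout list describing the feature layout (method, L, nFeatures,
#'   centerExcluded).
#' @slot version package version string recorded at training time.
#' @aliases SnoModel-class
#' @export SnoModel
#' @exportClass SnoModel
SnoModel <- setClass("SnoModel",
  slots = c(config = "ModelConfig", profile = "BiProfile", sv = "matrix",
            coefs = "numeric", rho = "numeric", flip = "numeric",
            layout = "list", version = "character"))

setValidity("SnoModel", function(object) {
  if (nrow(object@sv) != length(object@coefs)) {
    return("one dual coefficient per support vector required")
  }
  if (!object@flip %in% c(-1, 1)) return("flip must be +1 or -1")
  needed <- c("method", "L", "nFeatures", "centerExcluded")
  if (!all(needed %in% names(object@layout))) {
    return("layout must record method, L, nFeatures, centerExcluded")
  }
  if (ncol(object@sv) != object@layout$nFeatures) {
    return("support-vector width must match layout nFeatures")
  }
  TRUE
})

setMethod("show", "SnoModel", function(object) {
  cat(sprintf("SnoModel (%s encoding, L = %d, %d features): %d support vectors\n",
              object@layout$method, object@layout$L, object@layout$nFeatures,
              nrow(object@sv)))
  show(object@config)
})

#' MetricsReport: confusion counts and Sn/Sp/Acc/MCC
#'
#' Holds the confusion matrix of an evaluation together with sensitivity,
#' specificity and accuracy (as percentages) and the Matthews correlation
#' coefficient, plus a descriptor of the protocol that produced the counts.
#' Values are stored at full precision; \code{show} displays percentages to
#' 2 decimals and MCC to 4, rounding half up.
#'
#' @slot sn,sp,acc percentages in [0, 100].
#' @slot mcc Matthews correlation coefficient in [-1, 1].
#' @slot counts named integer vector (TP, FP, TN, FN).
#' @slot protocol character descriptor, e.g. "jackknife(scope=fold)".
#' @aliases MetricsReport-class
#' @export MetricsReport
#' @exportClass MetricsReport
MetricsReport <- setClass("MetricsReport",
  slots = c(sn = "numeric", sp = "numeric", acc = "numeric", mcc = "numeric",
            counts = "integer", protocol = "character"))

setValidity("MetricsReport", function(object) {
  if (!identical(names(object@counts), c("TP", "FP", "TN", "FN"))) {
    return("counts must be named TP, FP, TN, FN")
  }
  if (any(object@counts < 0L)) return("counts must be non-negative")
  rates <- c(object@sn, object@sp, object@acc)
  if (any(rates < -1e-9 | rates > 100 + 1e-9)) {
    return("Sn/Sp/Acc must be percentages in [0, 100]")
  }
  if (object@mcc < -1 - 1e-9 || object@mcc > 1 + 1e-9) {
    return("MCC must lie in [-1, 1]")
  }
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s]\n", object@protocol))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", object@counts["TP"],
              object@counts["FP"], object@counts["TN"], object@counts["FN"]))
  cat(sprintf("  Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.4f\n",
              roundHalfUp(object@sn, 2), roundHalfUp(object@sp, 2),
              roundHalfUp(object@acc, 2), roundHalfUp(object@mcc, 4)))
})

#' @rdname metricsFromCounts
#' @param x a \code{MetricsReport}
#' @export
confusionCounts <- function(x) x@counts

#' @rdname metricsFromCounts
#' @export
metricsVector <- function(x) {
  c(Sn = x@sn, Sp = x@sp, Acc = x@acc, MCC = x@mcc)
}
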