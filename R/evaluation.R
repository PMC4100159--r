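#' Performance metrics from a confusion matrix
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP) and accuracy
#' Acc = (TP+TN)/(TP+TN+FP+FN), all as percentages, and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Values are computed exactly and stored unrounded (display rounds half up
#' to 2 decimals for percentages, 4 for MCC). A zero factor in the MCC
#' denominator yields MCC = 0, the common convention for degenerate
#' confusion matrices.
#'
#' @param tp,fp,tn,fn non-negative integer counts. Alternatively pass a
#'   single named vector/list as \code{tp}.
#' @param protocol descriptor string recorded in the report.
#' @return a [MetricsReport-class].
#' @examples
#' metricsFromCounts(530, 560, 1008, 254)  # Acc 65.39%, MCC 0.3014
#' @export
metricsFromCounts <- function(tp, fp = NULL, tn = NULL, fn = NULL,
                              protocol = "counts") {
  if (is.null(fp) && (is.list(tp) || length(tp) == 4L)) {
    cc <- tp
    tp <- cc[["TP"]]; fp <- cc[["FP"]]; tn <- cc[["TN"]]; fn <- cc[["FN"]]
  }
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  counts <- structure(as.integer(counts), names = c("TP", "FP", "TN", "FN"))
  tp <- counts[[1]]; fp <- counts[[2]]; tn <- counts[[3]]; fn <- counts[[4]]
  total <- sum(counts)
  if (total == 0L) stop("empty confusion matrix")
  sn <- if (tp + fn > 0L) 100 * tp / (tp + fn) else 0
  sp <- if (tn + fp > 0L) 100 * tn / (tn + fp) else 0
  acc <- 100 * (tp + tn) / total
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  new("MetricsReport", sn = sn, sp = sp, acc = acc, mcc = mcc,
      counts = counts, protocol = protocol)
}

#' Reconstruct a confusion matrix from published rates
#'
#' Inverts the rounding of a published performance row: given sensitivity
#' (or accuracy) and specificity as percentages plus the class sizes, the
#' integer confusion matrix is recovered by half-up rounding:
#' TP = round(Sn * nPos / 100) and TN = round(Sp * nNeg / 100), or, when
#' accuracy is supplied instead of sensitivity,
#' TP = round(Acc * (nPos + nNeg) / 100) - TN. Remaining cells follow by
#' complement. This enables auditing printed Sn/Sp/Acc/MCC tables for
#' internal consistency.
#'
#' @param sn sensitivity percentage, or NULL if \code{acc} is given.
#' @param sp specificity percentage.
#' @param nPos,nNeg class sizes.
#' @param acc accuracy percentage, used when \code{sn} is NULL.
#' @return named integer vector (TP, FP, TN, FN).
#' @examples
#' countsFromRates(sn = 74.42, sp = 28.10, nPos = 43, nNeg = 121)
#' @export
countsFromRates <- function(sn = NULL, sp, nPos, nNeg, acc = NULL) {
  if (nPos < 1L || nNeg < 1L) stop("class sizes must be at least 1")
  checkRate <- function(x, what) {
    if (!is.null(x) && (x < 0 || x > 100)) {
      stop(what, " = ", x, " is not a percentage in [0, 100]")
    }
  }
  checkRate(sn, "Sn"); checkRate(sp, "Sp"); checkRate(acc, "Acc")
  tn <- roundHalfUp(sp * nNeg / 100)
  if (!is.null(sn)) {
    tp <- roundHalfUp(sn * nPos / 100)
  } else if (!is.null(acc)) {
    tp <- roundHalfUp(acc * (nPos + nNeg) / 100) - tn
  } else {
    stop("either sn or acc must be supplied")
  }
  cells <- c(TP = tp, FP = nNeg - tn, TN = tn, FN = nPos - tp)
  bad <- cells < 0 | cells > c(nPos, nNeg, nNeg, nPos)
  if (any(bad)) {
    stop("inconsistent rates: reconstructed ", names(cells)[bad][1], " = ",
         cells[bad][1], " outside [0, class size]")
  }
  structure(as.integer(cells), names = names(cells))
}

#' Audit a published performance-table row
#'
#' Reconstructs the integer confusion matrix from the printed rates and
#' class sizes via [countsFromRates()], recomputes all four metrics with
#' [metricsFromCounts()], and compares them (at the printed precision,
#' rounding half up) with any printed values supplied. Useful for checking
#' published Sn/Sp/Acc/MCC rows for internal consistency, e.g. detecting a
#' mistyped sensitivity.
#'
#' @inheritParams countsFromRates
#' @param printedSn,printedAcc,printedMcc optional printed values to check
#'   against the recomputation.
#' @return list with \code{counts}, \code{metrics} (a
#'   [MetricsReport-class]) and \code{consistent} (named logical for each
#'   printed value checked).
#' @export
auditTableRow <- function(sn = NULL, sp, nPos, nNeg, acc = NULL,
                          printedSn = NULL, printedAcc = NULL,
                          printedMcc = NULL) {
  counts <- countsFromRates(sn = sn, sp = sp, nPos = nPos, nNeg = nNeg,
                            acc = acc)
  rep <- metricsFromCounts(counts[["TP"]], counts[["FP"]], counts[["TN"]],
                           counts[["FN"]], protocol = "table-audit")
  consistent <- logical(0)
  if (!is.null(printedSn)) {
    consistent["Sn"] <- roundHalfUp(rep@sn, 2) == printedSn
  }
  if (!is.null(printedAcc)) {
    consistent["Acc"] <- roundHalfUp(rep@acc, 2) == printedAcc
  }
  if (!is.null(printedMcc)) {
    consistent["MCC"] <- roundHalfUp(rep@mcc, 4) == printedMcc
  }
  list(counts = counts, metrics = rep, consistent = consistent)
}

## Tally held-out predictions into a confusion vector.
tallyCounts <- function(truth, pred) {
  c(TP = sum(truth == 1L & pred == 1L),
    FP = sum(truth == -1L & pred == 1L),
    TN = sum(truth == -1L & pred == -1L),
    FN = sum(truth == 1L & pred == -1L))
}

## Remove one window's contribution from a PositionCounts (for the O(1)
## per-fold profile update in the jackknife).
dropWindowFromCounts <- function(counts, window) {
  letters <- strsplit(window, "", fixed = TRUE)[[1]]
  idx <- match(letters, AA20)
  keep <- !is.na(idx)
  m <- counts@counts
  m[cbind(idx[keep], which(keep))] <- m[cbind(idx[keep], which(keep))] - 1L
  new("PositionCounts", counts = m, n = counts@n - 1L,
      effectiveN = as.integer(colSums(m)))
}

#' Leave-one-out (jackknife) evaluation
#'
#' For each window in turn: hold it out, rebuild the bi-profile and refit
#' the classifier on the remaining windows, predict the held-out window,
#' and pool the resulting confusion counts. With the default
#' \code{profileScope = "fold"} the bi-profile is recomputed for every fold
#' so no information about the held-out window leaks into its encoding;
#' \code{profileScope = "global"} builds the profile once on all windows
#' (the classifier is still refit per fold). The global mode deliberately
#' mimics a leaky protocol and is provided as a diagnostic: on
#' label-shuffled data it yields systematically higher apparent MCC than
#' the fold-scoped protocol.
#'
#' @param windows a [PeptideWindowSet-class] with at least 2 windows per
#'   class.
#' @param method profile method, "anbpb" or "bpb".
#' @param config a [ModelConfig-class].
#' @param profileScope "fold" (default, leakage-free) or "global".
#' @param p background per-residue probability.
#' @return a [MetricsReport-class] pooled over all folds.
#' @export
jackknife <- function(windows, method = c("anbpb", "bpb"),
                      config = modelConfig(),
                      profileScope = c("fold", "global"), p = 1 / 20) {
  method <- match.arg(method)
  profileScope <- match.arg(profileScope)
  labels <- windows@label
  if (sum(labels == 1L) < 2L || sum(labels == -1L) < 2L) {
    stop("jackknife requires at least 2 windows per class ",
         "(a fold would lose an entire class)")
  }
  n <- length(windows)
  res <- windows@residues
  cPosAll <- countPositions(res[labels == 1L])
  cNegAll <- countPositions(res[labels == -1L])
  globalProfile <- biProfileFromCounts(cPosAll, cNegAll, method, p)
  pred <- integer(n)
  for (i in seq_len(n)) {
    if (profileScope == "fold") {
      if (labels[i] == 1L) {
        prof <- biProfileFromCounts(dropWindowFromCounts(cPosAll, res[i]),
                                    cNegAll, method, p)
      } else {
        prof <- biProfileFromCounts(cPosAll,
                                    dropWindowFromCounts(cNegAll, res[i]),
                                    method, p)
      }
    } else {
      prof <- globalProfile
    }
    feats <- encodeDataset(res, prof)
    fit <- trainModel(feats[-i, , drop = FALSE], labels[-i], config,
                      profile = prof, layout = attr(feats, "layout"))
    pred[i] <- predict(fit, feats[i, , drop = FALSE])
  }
  counts <- tallyCounts(labels, pred)
  metricsFromCounts(counts[["TP"]], counts[["FP"]], counts[["TN"]],
                    counts[["FN"]],
                    protocol = sprintf("jackknife(scope=%s,method=%s)",
                                       profileScope, method))
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs k-fold cross-validation \code{repeats} times with a fresh
#' stratified shuffle per repeat drawn from a seeded generator. Within each
#' fold the bi-profile is built on the training part only (or once per run
#' globally, with \code{profileScope = "global"}) and the classifier refit;
#' the per-repeat metrics are pooled from the fold confusion counts, and
#' their mean and standard deviation across repeats are reported.
#'
#' @param windows a [PeptideWindowSet-class].
#' @param k number of folds (default 10); must not exceed either class size,
#'   except for the leave-one-out identity k = n (each window its own fold),
#'   which reproduces the [jackknife()] counts when \code{repeats = 1}.
#' @param repeats number of repeated runs (default 50).
#' @param seed integer seed for the shuffles.
#' @param method profile method.
#' @param config a [ModelConfig-class].
#' @param profileScope "fold" (default) or "global".
#' @param p background per-residue probability.
#' @return list with \code{mean} (a [MetricsReport-class] of mean-pooled
#'   counts, metrics averaged over repeats), \code{sd} (named vector of
#'   metric standard deviations across repeats), and \code{perRepeat}
#'   (data.frame of per-repeat Sn/Sp/Acc/MCC).
#' @export
repeatedKFold <- function(windows, k = 10L, repeats = 50L, seed = 1L,
                          method = c("anbpb", "bpb"), config = modelConfig(),
                          profileScope = c("fold", "global"), p = 1 / 20) {
  method <- match.arg(method)
  profileScope <- match.arg(profileScope)
  labels <- windows@label
  loo <- k == length(windows)  # k = n: leave-one-out, stratification moot
  if (!loo && min(sum(labels == 1L), sum(labels == -1L)) < k) {
    stop("k = ", k, " exceeds the smaller class size")
  }
  res <- windows@residues
  perRepeat <- matrix(NA_real_, nrow = repeats, ncol = 4L,
                      dimnames = list(NULL, c("Sn", "Sp", "Acc", "MCC")))
  countsTotal <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (r in seq_len(repeats)) {
    foldId <- if (loo) seq_along(labels) else
      makeStratifiedFolds(labels, k, seed = seed + r - 1L)
    counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    globalProfile <- if (profileScope == "global") {
      buildBiProfile(res[labels == 1L], res[labels == -1L], method, p)
    }
    for (f in seq_len(k)) {
      test <- foldId == f
      prof <- if (profileScope == "fold") {
        buildBiProfile(res[!test & labels == 1L], res[!test & labels == -1L],
                       method, p)
      } else {
        globalProfile
      }
      feats <- encodeDataset(res, prof)
      fit <- trainModel(feats[!test, , drop = FALSE], labels[!test], config,
                        profile = prof, layout = attr(feats, "layout"))
      pred <- predict(fit, feats[test, , drop = FALSE])
      counts <- counts + tallyCounts(labels[test], pred)
    }
    rep_ <- metricsFromCounts(counts[["TP"]], counts[["FP"]], counts[["TN"]],
                              counts[["FN"]])
    perRepeat[r, ] <- metricsVector(rep_)
    countsTotal <- countsTotal + counts
  }
  meanCounts <- as.integer(roundHalfUp(countsTotal / repeats))
  meanReport <- new("MetricsReport",
                    sn = mean(perRepeat[, "Sn"]), sp = mean(perRepeat[, "Sp"]),
                    acc = mean(perRepeat[, "Acc"]),
                    mcc = mean(perRepeat[, "MCC"]),
                    counts = structure(meanCounts,
                                       names = c("TP", "FP", "TN", "FN")),
                    protocol = sprintf("kfold(k=%d,repeats=%d,seed=%d,scope=%s)",
                                       k, repeats, seed, profileScope))
  sds <- apply(perRepeat, 2L, sd)
  list(mean = meanReport, sd = sds,
       perRepeat = as.data.frame(perRepeat))
}
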