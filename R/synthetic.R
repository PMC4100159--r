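#' Specification for a synthetic window dataset
#'
#' Describes a labeled peptide-window dataset with planted position-specific
#' enrichments, emulating the structure real S-nitrosylation training sets
#' exhibit (a handful of residues mildly enriched or depleted around the
#' modified cysteine). Negative-class residues are drawn independently from
#' the background distribution at every non-center position; the positive
#' class draws from a modified distribution at each motif position in which
#' the planted residue's probability is exactly \code{rho} times its
#' background probability (the remaining residues are renormalized to the
#' leftover mass), so the planted positional frequency ratio equals
#' \code{rho} by construction. \code{rho = Inf} plants the residue
#' deterministically, and \code{exclusive = TRUE} additionally removes it
#' from the negative background at that position, making the classes
#' perfectly separable on that column.
#'
#' @param nPos,nNeg class sizes.
#' @param L odd window length (default 21).
#' @param background probability vector over the 20 amino acids in the
#'   fixed order (default uniform 1/20; [swissprotBackground] ships as a
#'   realistic alternative).
#' @param motif data.frame with columns \code{position} (1-based, not the
#'   center), \code{residue}, \code{rho}, and optionally \code{exclusive};
#'   NULL for no planted signal.
#' @param padFraction probability that a window is terminally truncated and
#'   "X"-padded (default 0).
#' @param seed integer seed; the dataset is a pure function of the spec.
#' @return a validated list of class \code{syntheticSpec}.
#' @export
syntheticSpec <- function(nPos, nNeg, L = 21L, background = rep(1 / 20, 20L),
                          motif = NULL, padFraction = 0, seed = 1L) {
  L <- checkOddLength(L)
  stopifnot(nPos >= 1L, nNeg >= 1L, length(background) == 20L,
            all(background > 0), abs(sum(background) - 1) < 1e-8,
            padFraction >= 0, padFraction <= 1)
  if (!is.null(motif)) {
    stopifnot(is.data.frame(motif),
              all(c("position", "residue", "rho") %in% names(motif)))
    if (is.null(motif$exclusive)) motif$exclusive <- FALSE
    center <- (L + 1L) / 2L
    if (any(motif$position == center)) {
      stop("motif positions must not be the center (it is fixed to 'C')")
    }
    if (any(motif$position < 1L | motif$position > L)) {
      stop("motif position outside the window")
    }
    if (any(!motif$residue %in% AA20)) stop("motif residue not an amino acid")
    if (any(motif$rho <= 0)) stop("motif rho must be positive")
    p0 <- background[match(motif$residue, AA20)]
    finite <- is.finite(motif$rho)
    if (any(motif$rho[finite] * p0[finite] >= 1)) {
      stop("rho * background probability must stay below 1 ",
           "(use rho = Inf for a deterministic plant)")
    }
  }
  structure(list(nPos = as.integer(nPos), nNeg = as.integer(nNeg), L = L,
                 background = background, motif = motif,
                 padFraction = padFraction, seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' SwissProt-like amino-acid background frequencies
#'
#' Approximate average residue frequencies of well-annotated protein
#' sequence databases, normalized to sum to 1, in the package's fixed
#' amino-acid order; an alternative to the uniform background for
#' generating synthetic windows.
#'
#' @format named numeric vector of length 20.
#' @export
swissprotBackground <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.71, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.85,
         W = 1.10, Y = 2.92)
  f / sum(f)
})

## Per-position sampling distribution for the positive class.
positiveColumnDistribution <- function(background, residue, rho) {
  i <- match(residue, AA20)
  out <- background
  if (is.infinite(rho)) {
    out[] <- 0
    out[i] <- 1
  } else {
    target <- rho * background[i]
    out[-i] <- background[-i] * (1 - target) / (1 - background[i])
    out[i] <- target
  }
  out
}

#' Generate a synthetic labeled window dataset
#'
#' Draws \code{nPos} positive and \code{nNeg} negative windows according to
#' a [syntheticSpec()]: centers fixed to "C", residues sampled per position,
#' and a \code{padFraction} share of windows truncated at a uniformly drawn
#' terminal length and filled with "X". Protein ids \code{sim<k>} and the
#' center position within the unpadded sequence are recorded, so fixture
#' FASTA / site-table pairs regenerate the same windows. The result is a
#' pure function of the spec (including its seed).
#'
#' @param spec a [syntheticSpec()].
#' @return a [PeptideWindowSet-class] of nPos + nNeg windows (positives
#'   first).
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  L <- spec$L
  center <- (L + 1L) / 2L
  flank <- (L - 1L) %/% 2L
  n <- spec$nPos + spec$nNeg
  labels <- rep(c(1L, -1L), c(spec$nPos, spec$nNeg))
  ## per-class, per-position distributions
  posDist <- negDist <- matrix(spec$background, nrow = 20L, ncol = L)
  if (!is.null(spec$motif)) {
    for (m in seq_len(nrow(spec$motif))) {
      j <- spec$motif$position[m]
      posDist[, j] <- positiveColumnDistribution(spec$background,
                                                 spec$motif$residue[m],
                                                 spec$motif$rho[m])
      if (isTRUE(spec$motif$exclusive[m])) {
        i <- match(spec$motif$residue[m], AA20)
        d <- spec$background
        d[i] <- 0
        negDist[, j] <- d / sum(d)
      }
    }
  }
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(spec$seed)
  mat <- matrix("", nrow = n, ncol = L)
  for (j in seq_len(L)) {
    if (j == center) {
      mat[, j] <- "C"
      next
    }
    mat[labels == 1L, j] <- sample(AA20, spec$nPos, replace = TRUE,
                                   prob = posDist[, j])
    mat[labels == -1L, j] <- sample(AA20, spec$nNeg, replace = TRUE,
                                    prob = negDist[, j])
  }
  ## terminal truncation: replace a random-length prefix or suffix with "X"
  padded <- runif(n) < spec$padFraction
  padLeft <- integer(n)
  padRight <- integer(n)
  for (i in which(padded)) {
    k <- sample.int(flank, 1L)
    if (runif(1) < 0.5) {
      mat[i, seq_len(k)] <- PAD
      padLeft[i] <- k
    } else {
      mat[i, seq.int(L - k + 1L, L)] <- PAD
      padRight[i] <- k
    }
  }
  peptideWindowSet(apply(mat, 1L, paste, collapse = ""), labels,
                   proteinId = sprintf("sim%d", seq_len(n)),
                   position = center - padLeft)
}

## The canonical fixture definitions: seeds and study conditions are fixed
## constants of the package, not tuning knobs.
fixtureSpecs <- function(L = 21L) {
  list(
    null = syntheticSpec(200L, 200L, L = L, motif = NULL, seed = 11L),
    `weak-motif` = syntheticSpec(
      2000L, 2000L, L = L,
      motif = data.frame(position = 3L, residue = "K", rho = 3),
      seed = 22L),
    separable = syntheticSpec(
      100L, 100L, L = L,
      motif = data.frame(position = 5L, residue = "W", rho = Inf,
                         exclusive = TRUE),
      seed = 33L),
    padded = syntheticSpec(
      100L, 100L, L = L,
      motif = data.frame(position = 3L, residue = "K", rho = 3),
      padFraction = 0.5, seed = 44L))
}

#' Generate one canonical fixture dataset
#'
#' The package ships four canonical synthetic fixtures used throughout its
#' test-suite: \code{"null"} (no planted signal, 200+200), the
#' \code{"weak-motif"} (K at position 3 enriched threefold in positives,
#' 2000+2000), \code{"separable"} (W planted deterministically at position 5
#' in every positive and excluded from negatives, 100+100), and
#' \code{"padded"} (the weak motif plus 50% terminally truncated windows,
#' 100+100). Seeds are fixed constants.
#'
#' @param name one of "null", "weak-motif", "separable", "padded".
#' @param L odd window length (default 21).
#' @return a [PeptideWindowSet-class].
#' @export
fixtureDataset <- function(name = c("null", "weak-motif", "separable",
                                    "padded"), L = 21L) {
  name <- match.arg(name)
  generateDataset(fixtureSpecs(L)[[name]])
}

#' Write the canonical fixture suite to disk
#'
#' For each canonical fixture, writes the window TSV, a FASTA of the
#' (unpadded) source sequences, and a site-annotation TSV, plus a
#' \code{manifest.json} recording the generator settings, seeds and summary
#' statistics (class sizes and, where a motif is planted, the estimated
#' propensity at the planted cell). Reruns are byte-identical.
#'
#' @param outDir output directory (created if needed).
#' @param L odd window length.
#' @return invisibly, the manifest as a list.
#' @export
makeFixtureSuite <- function(outDir, L = 21L) {
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  specs <- fixtureSpecs(L)
  manifest <- list()
  for (name in names(specs)) {
    spec <- specs[[name]]
    windows <- generateDataset(spec)
    base <- file.path(outDir, name)
    writeWindows(windows, paste0(base, ".windows.tsv"))
    seqs <- gsub(PAD, "", windows@residues, fixed = TRUE)
    names(seqs) <- windows@proteinId
    writeProteins(seqs, paste0(base, ".fasta"))
    siteTab <- data.frame(protein_id = windows@proteinId,
                          position = windows@position,
                          label = windows@label)
    con <- file(paste0(base, ".sites.tsv"), "w")
    writeLines("protein_id\tposition\tlabel", con)
    writeLines(paste(siteTab$protein_id, siteTab$position, siteTab$label,
                     sep = "\t"), con)
    close(con)
    entry <- list(seed = spec$seed, nPos = spec$nPos, nNeg = spec$nNeg,
                  L = spec$L, padFraction = spec$padFraction)
    if (!is.null(spec$motif)) {
      prop <- relativePropensity(
        countPositions(windows[which(windows@label == 1L)]),
        countPositions(windows[which(windows@label == -1L)]))
      entry$motif <- spec$motif
      entry$plantedPropensity <- unname(
        prop@r[match(spec$motif$residue, AA20)[1], spec$motif$position[1]])
    }
    manifest[[name]] <- entry
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
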