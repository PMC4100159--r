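#' @importFrom methods new validObject is slot show
#' @importFrom stats pnorm sd predict
#' @importFrom utils read.delim write.table packageVersion
NULL

## The 20 standard amino acids in the fixed alphabetical order used for all
## position-count and profile matrices.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Terminal-padding character; the window alphabet is AA20 plus "X".
PAD <- "X"
WINDOW_ALPHABET <- c(AA20, PAD)

## Physicochemical residue partitions used for the two pseudo-amino-acid
## composition features. The "positively charged" labelling follows the
## published partition verbatim even though it is chemically unconventional;
## the complements (G and E classes) are dependent and therefore not encoded.
CLASS_A <- c("A", "C", "D", "E", "H", "L", "P", "Q", "S", "V", "W")
CLASS_H <- c("C", "D", "G", "N", "P", "S", "T", "W", "Y")

#' Round half away from zero
#'
#' Deterministic half-up rounding at a fixed number of decimal digits,
#' matching the convention used when auditing published performance tables
#' (base \code{round} rounds half to even). A small guard compensates for
#' binary representation of decimal rates (e.g. 67.60 * 784 / 100).
#'
#' @param x numeric vector.
#' @param digits integer, decimal digits to keep.
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(0.5)        # 1, where round(0.5) is 0
#' roundHalfUp(2.345, 2)   # 2.35
#' @export
roundHalfUp <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

## Split window strings into an n x L character matrix.
residueMatrix <- function(residues) {
  if (length(residues) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = 0L))
  }
  L <- unique(nchar(residues))
  if (length(L) != 1L) {
    stop("windows have mixed lengths: ", paste(L, collapse = ", "))
  }
  matrix(unlist(strsplit(residues, "", fixed = TRUE), use.names = FALSE),
         nrow = length(residues), ncol = L, byrow = TRUE)
}

checkOddLength <- function(L) {
  if (length(L) != 1L || is.na(L) || L < 1L || L %% 2L != 1L) {
    stop("window length L must be a positive odd integer, got ", L)
  }
  as.integer(L)
}
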