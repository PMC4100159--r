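#' Read protein sequences from FASTA
#'
#' Reads a protein FASTA file into a named character vector of uppercase
#' sequences. Sequences may contain only the 20 standard amino-acid letters
#' plus "X" for unknown residues; anything else (digits, gaps, ambiguity
#' codes) is rejected. Ids must be unique; the id is the first whitespace
#' token of the description line.
#'
#' @param path path to a FASTA file.
#' @return named character vector (names = protein ids). Empty files yield
#'   an empty vector.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDC"), fa)
#' readProteins(fa)
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(aas)))
  ids <- sub("\\s.*$", "", names(aas))
  if (length(ids) && anyDuplicated(ids)) {
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- vapply(seqs, function(s) {
    letters <- strsplit(s, "", fixed = TRUE)[[1]]
    any(!letters %in% WINDOW_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) contain letters outside the 20-amino-acid + 'X' alphabet: ",
         paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param proteins named character vector of sequences.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeProteins <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(proteins), path)
  invisible(path)
}

#' Read a site-annotation table
#'
#' Reads a TSV with columns \code{protein_id}, \code{position} (1-based
#' index of the candidate cysteine) and \code{label}, normalizing labels to
#' +1/-1 via an alias map. Lines starting with "#" are ignored.
#'
#' @param path path to the TSV.
#' @param labelAliases named integer vector mapping label tokens to +1/-1.
#' @return data.frame with columns proteinId (character), position
#'   (integer), label (integer +1/-1).
#' @export
readSiteTable <- function(path,
                          labelAliases = c("1" = 1L, "+1" = 1L, "-1" = -1L,
                                           "pos" = 1L, "neg" = -1L)) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE)
  needed <- c("protein_id", "position", "label")
  if (!all(needed %in% names(tab))) {
    stop("site table must have columns protein_id, position, label; found: ",
         paste(names(tab), collapse = ", "))
  }
  n <- nrow(tab)
  pos <- suppressWarnings(as.integer(tab$position))
  badPos <- which(is.na(pos) | as.character(pos) != sub("^\\+", "", tab$position) |
                  pos < 1L)
  if (length(badPos)) {
    stop("row ", badPos[1], ": position '", tab$position[badPos[1]],
         "' is not a positive (1-based) integer")
  }
  lab <- unname(labelAliases[tab$label])
  badLab <- which(is.na(lab))
  if (length(badLab)) {
    stop("row ", badLab[1], ": unknown label token '", tab$label[badLab[1]], "'")
  }
  data.frame(proteinId = tab$protein_id, position = pos, label = as.integer(lab),
             stringsAsFactors = FALSE)
}

#' Extract a fixed-length window around a site
#'
#' Returns the L-mer covering (L-1)/2 residues on each side of the given
#' 1-based position; positions before the first or after the last residue of
#' the protein are filled with the padding letter "X". By default the
#' central residue must be a cysteine.
#'
#' @param sequence protein sequence (single string).
#' @param position 1-based site position within \code{sequence}.
#' @param L odd window length (default 21).
#' @param allowAnyCenter if TRUE, skip the cysteine-center check.
#' @param proteinId id used in error messages.
#' @return the window string of length L.
#' @examples
#' extractWindow("CDEFGHIKLMN", 1)          # ten leading "X"s
#' extractWindow("AC", 2, L = 5)            # "XACXX"
#' @export
extractWindow <- function(sequence, position, L = 21L,
                          allowAnyCenter = FALSE, proteinId = "?") {
  L <- checkOddLength(L)
  len <- nchar(sequence)
  if (position < 1L || position > len) {
    stop("position ", position, " outside protein ", proteinId,
         " (length ", len, ")")
  }
  center <- substr(sequence, position, position)
  if (!allowAnyCenter && center != "C") {
    stop("residue at ", proteinId, ":", position, " is '", center,
         "', not the cysteine required at a window center")
  }
  flank <- (L - 1L) %/% 2L
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(1L, lo), min(len, hi))
  paste0(strrep(PAD, max(0L, 1L - lo)), core, strrep(PAD, max(0L, hi - len)))
}

#' Extract a labeled window dataset
#'
#' One window per annotation row, in input order, with labels and
#' provenance carried through.
#'
#' @param proteins named character vector from [readProteins()].
#' @param sites data.frame from [readSiteTable()].
#' @param L odd window length.
#' @param allowAnyCenter passed to [extractWindow()].
#' @return a [PeptideWindowSet-class].
#' @export
extractDataset <- function(proteins, sites, L = 21L, allowAnyCenter = FALSE) {
  missing <- setdiff(sites$proteinId, names(proteins))
  if (length(missing)) {
    stop("annotation(s) reference unknown protein id(s): ",
         paste(unique(missing), collapse = ", "))
  }
  res <- vapply(seq_len(nrow(sites)), function(i) {
    extractWindow(proteins[[sites$proteinId[i]]], sites$position[i], L = L,
                  allowAnyCenter = allowAnyCenter,
                  proteinId = sites$proteinId[i])
  }, character(1))
  peptideWindowSet(res, sites$label, sites$proteinId, sites$position)
}

#' Remove exact duplicate windows
#'
#' Keeps the first occurrence of each (residues, label) pair. Windows whose
#' residues recur with the opposite label are all kept, with a warning:
#' resolving such conflicts is the caller's responsibility. The number of
#' removed duplicates is reported with a message.
#'
#' @param windows a [PeptideWindowSet-class].
#' @return the deduplicated [PeptideWindowSet-class].
#' @export
dedupExact <- function(windows) {
  key <- paste(windows@residues, windows@label, sep = "|")
  keep <- !duplicated(key)
  removed <- sum(!keep)
  if (removed > 0L) message("dedupExact: removed ", removed, " exact duplicate(s)")
  out <- windows[which(keep)]
  conflict <- intersect(out@residues[out@label == 1L],
                        out@residues[out@label == -1L])
  if (length(conflict)) {
    warning(length(conflict),
            " window sequence(s) occur with both labels; all kept")
  }
  out
}

windowHeader <- "residues\tlabel\tprotein_id\tposition"

#' Read / write window TSV
#'
#' The window serialization dialect is a TSV with header columns
#' \code{residues}, \code{label}, \code{protein_id}, \code{position};
#' comment lines starting with "#" are permitted before the header and
#' ignored on read, so files written by the command-line tools (which
#' prepend a provenance header) round-trip.
#'
#' @param windows a [PeptideWindowSet-class].
#' @param path file path.
#' @param headerLines optional character vector of "#"-prefixed comment
#'   lines written before the header.
#' @return \code{readWindows}: a [PeptideWindowSet-class];
#'   \code{writeWindows}: invisibly, \code{path}.
#' @export
writeWindows <- function(windows, path, headerLines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(headerLines)) writeLines(headerLines, con)
  writeLines(windowHeader, con)
  if (length(windows)) {
    writeLines(paste(windows@residues, windows@label,
                     ifelse(is.na(windows@proteinId), "NA", windows@proteinId),
                     ifelse(is.na(windows@position), "NA", windows@position),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeWindows
#' @export
readWindows <- function(path) {
  if (!file.exists(path)) stop("window TSV not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE)
  needed <- c("residues", "label", "protein_id", "position")
  if (!all(needed %in% names(tab))) {
    stop("window TSV must have header columns residues, label, protein_id, position")
  }
  peptideWindowSet(tab$residues, as.integer(tab$label),
                   ifelse(tab$protein_id == "NA", NA_character_, tab$protein_id),
                   suppressWarnings(as.integer(tab$position)))
}
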