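#' The 22-letter amino-acid alphabet
#'
#' Column order of the residue channels of an encoded protein: the 20
#' standard amino acids in alphabetical one-letter order, then U
#' (selenocysteine) and O (pyrrolysine). The mask channel is always
#' column 23 and is not part of the alphabet. A different ordering (or
#' any other 22 distinct letters) may be passed to the encoding
#' functions, but all components of one model must share it.
#'
#' @return character vector of 22 single letters.
#' @examples
#' trioAlphabet()
#' @export
trioAlphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "U", "O")
}

#' Read and validate protein sequences from FASTA
#'
#' Sequences are upper-cased and validated against the 22-letter alphabet
#' and a maximum length. Records that fail validation are either rejected
#' with an error (default) or skipped with a warning, per \code{policy}.
#' A minimum length may additionally be enforced with \code{minLength}
#' (dataset-level filtering; off by default so short test sequences stay
#' usable).
#'
#' @param path FASTA file.
#' @param policy \code{"reject"} (error on an invalid record) or
#'   \code{"skip"} (drop it with a warning).
#' @param lmax maximum sequence length (default 1500).
#' @param minLength optional minimum length filter, applied with the same
#'   policy; e.g. 150 for corpus-style filtering.
#' @param alphabet residue alphabet, see \code{\link{trioAlphabet}}.
#' @return a named \code{Biostrings::AAStringSet}.
#' @export
readProteinFasta <- function(path, policy = c("reject", "skip"),
                             lmax = 1500L, minLength = NULL,
                             alphabet = trioAlphabet()) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stopf("malformed FASTA '%s': %s",
                                             path, conditionMessage(e)))
  if (length(seqs) == 0L) stopf("no FASTA records in %s", path)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  validateRecords(seqs, policy = policy, lmax = lmax,
                  minLength = minLength, alphabet = alphabet)
}

# shared record validation for FASTA input and in-memory sets
validateRecords <- function(seqs, policy, lmax, minLength, alphabet) {
  chars <- strsplit(as.character(seqs), "")
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    bad <- setdiff(unique(chars[[i]]), alphabet)
    problem <- NULL
    if (length(bad))
      problem <- sprintf("record '%s' contains illegal residue(s) %s",
                         id, paste(bad, collapse = ","))
    else if (length(chars[[i]]) < 1L)
      problem <- sprintf("record '%s' is empty", id)
    else if (length(chars[[i]]) > lmax)
      problem <- sprintf("record '%s' has length %d > lmax %d",
                         id, length(chars[[i]]), lmax)
    else if (!is.null(minLength) && length(chars[[i]]) < minLength)
      problem <- sprintf("record '%s' has length %d < minimum %d",
                         id, length(chars[[i]]), minLength)
    if (!is.null(problem)) {
      if (policy == "reject") stopf("%s", problem)
      warnf("skipping: %s", problem)
      keep[i] <- FALSE
    }
  }
  if (anyDuplicated(names(seqs)[keep]))
    stopf("duplicate sequence ids: %s",
          paste(unique(names(seqs)[keep][duplicated(names(seqs)[keep])]),
                collapse = ", "))
  seqs[keep]
}

#' Write protein sequences to FASTA
#'
#' @param seqs a named \code{AAStringSet} (or named character vector).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is.character(seqs))
    seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' One-hot encode a protein sequence
#'
#' Builds the \code{lmax x 23} one-hot matrix X of an
#' \linkS4class{EncodedProtein}: rows \code{1..len} select the residue's
#' alphabet column and rows \code{len+1..lmax} are padding, one-hot on
#' the mask column with the mask bit set. The empty sequence encodes as
#' the fully-masked matrix (the "blank" partner of single-protein
#' training cases).
#'
#' @param residues a character string over the alphabet (possibly "").
#' @param lmax fixed encoded length; sequence must not exceed it.
#' @param alphabet residue alphabet (column order).
#' @return an \linkS4class{EncodedProtein}.
#' @examples
#' enc <- encodeProtein("ACDK", lmax = 8)
#' trueLength(enc)
#' colSums(onehot(enc))
#' @export
encodeProtein <- function(residues, lmax = 1500L, alphabet = trioAlphabet()) {
  residues <- as.character(residues)
  stopifnot(length(residues) == 1L)
  len <- nchar(residues)
  lmax <- as.integer(lmax)
  if (len > lmax) stopf("sequence length %d exceeds lmax %d", len, lmax)
  cols <- rep.int(23L, lmax)
  if (len > 0L) {
    letters <- strsplit(residues, "")[[1]]
    idx <- match(letters, alphabet)
    if (anyNA(idx))
      stopf("illegal residue '%s' (not in the 22-letter alphabet)",
            letters[which(is.na(idx))[1]])
    cols[seq_len(len)] <- idx
  }
  X <- matrix(0, nrow = lmax, ncol = 23L)
  X[cbind(seq_len(lmax), cols)] <- 1
  new("EncodedProtein", X = X, B = cols == 23L,
      trueLength = len, alphabet = alphabet)
}

#' Mask residue positions of an encoding
#'
#' Replaces the listed rows by the mask one-hot and sets their mask bits;
#' the input object is unchanged and re-masking an already masked
#' position is a no-op. Positions are 1-based and must lie inside the
#' represented sequence (not in the padding). Masking every position
#' yields, bit for bit, the encoding of the empty sequence.
#'
#' @param enc an \linkS4class{EncodedProtein}.
#' @param positions integer vector of 1-based positions, each
#'   \code{<= trueLength(enc)}.
#' @return a new \linkS4class{EncodedProtein}.
#' @export
maskPositions <- function(enc, positions) {
  stopifnot(is(enc, "EncodedProtein"))
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(enc)
  if (any(positions < 1L) || any(positions > enc@trueLength))
    stopf("positions must lie in 1..trueLength (%d); got %s",
          enc@trueLength,
          paste(positions[positions < 1L | positions > enc@trueLength],
                collapse = ","))
  X <- enc@X
  B <- enc@B
  X[positions, ] <- 0
  X[positions, 23L] <- 1
  B[positions] <- TRUE
  tl <- if (all(B)) 0L else enc@trueLength
  new("EncodedProtein", X = X, B = B, trueLength = tl,
      alphabet = enc@alphabet)
}

#' Construct a PairList
#'
#' @param idA,idB character vectors of protein identifiers.
#' @param label optional character vector of class labels
#'   (\code{"interacting"}, \code{"negative"}, \code{"single_protein"})
#'   or \code{NA} for unlabelled prediction input.
#' @return a \linkS4class{PairList}.
#' @export
PairList <- function(idA = character(), idB = character(),
                     label = rep(NA_character_, length(idA))) {
  new("PairList", entries = data.frame(
    idA = as.character(idA), idB = as.character(idB),
    label = as.character(label), stringsAsFactors = FALSE))
}

#' Read a pair list from TSV
#'
#' Expects a tab-delimited file with two (prediction input) or three
#' (labelled input) columns: \code{idA}, \code{idB}\code{[, label]}.
#' Lines starting with \code{#} are comments/header. Every identifier
#' must resolve against \code{sequences}; unresolved ids are reported
#' with their row numbers.
#'
#' @param path TSV file.
#' @param sequences named \code{AAStringSet} (or named character vector)
#'   the identifiers must resolve against.
#' @param labeled TRUE to require labels, FALSE to forbid them, NA
#'   (default) to accept either.
#' @return a \linkS4class{PairList}.
#' @export
readPairs <- function(path, sequences, labeled = NA) {
  if (!file.exists(path)) stopf("pair file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(PairList())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L))
    stopf("row %d: need at least 2 tab-separated columns",
          rows[which(ncols < 2L)[1]])
  hasLabel <- ncols >= 3L
  if (isTRUE(labeled) && !all(hasLabel))
    stopf("row %d: label column required", rows[which(!hasLabel)[1]])
  if (isFALSE(labeled) && any(hasLabel))
    stopf("row %d: unexpected label column", rows[which(hasLabel)[1]])
  idA <- vapply(parts, `[[`, "", 1L)
  idB <- vapply(parts, `[[`, "", 2L)
  label <- ifelse(hasLabel, vapply(parts, function(p)
    if (length(p) >= 3L) p[[3L]] else NA_character_, ""), NA_character_)
  badLab <- !is.na(label) & !label %in% tripartiteClasses()
  if (any(badLab))
    stopf("row %d: unknown label '%s' (expected %s)",
          rows[which(badLab)[1]], label[which(badLab)[1]],
          paste(tripartiteClasses(), collapse = "/"))
  known <- names(sequences)
  miss <- !(idA %in% known) | !(idB %in% known)
  if (any(miss)) {
    i <- which(miss)[1]
    unknown <- setdiff(c(idA[i], idB[i]), known)
    stopf("row %d: unresolved id '%s'", rows[i], unknown[1])
  }
  PairList(idA, idB, label)
}

#' Write a pair list to TSV
#'
#' @param pairs a \linkS4class{PairList}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePairs <- function(pairs, path) {
  e <- pairFrame(pairs)
  cols <- if (all(is.na(e$label))) e[, c("idA", "idB")] else e
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

#' @rdname EncodedProtein-class
#' @export
setMethod("trueLength", "EncodedProtein", function(x) x@trueLength)

#' @rdname EncodedProtein-class
#' @export
setMethod("maskBits", "EncodedProtein", function(x) x@B)

#' @rdname EncodedProtein-class
#' @export
setMethod("onehot", "EncodedProtein", function(x) x@X)

setMethod("show", "EncodedProtein", function(object) {
  cat(sprintf("EncodedProtein: %d x 23 one-hot, trueLength %d, %d masked\n",
              nrow(object@X), object@trueLength, sum(object@B)))
})

#' @rdname PairList-class
#' @export
setMethod("pairFrame", "PairList", function(x) x@entries)

#' @rdname PairList-class
#' @export
setMethod("pairLabels", "PairList", function(x) x@entries$label)

#' @rdname PairList-class
#' @param x a \code{PairList}.
#' @export
setMethod("length", "PairList", function(x) nrow(x@entries))

#' @rdname PairList-class
#' @param i index vector.
#' @export
setMethod("[", "PairList", function(x, i) {
  new("PairList", entries = x@entries[i, , drop = FALSE])
})

setMethod("show", "PairList", function(object) {
  tab <- table(factor(object@entries$label, levels = tripartiteClasses()),
               useNA = "ifany")
  cat(sprintf("PairList: %d pairs (%s)\n", nrow(object@entries),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})
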