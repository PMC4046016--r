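#' The mdmi symbol alphabet
#'
#' Twenty standard amino acids (one-letter codes, alphabetical) followed by
#' the gap symbol \code{"-"}. Every alignment is encoded against this fixed
#' 21-letter alphabet; ambiguous or non-standard letters (B, J, O, U, X, Z)
#' and the \code{"."} gap are collapsed into the gap class so that
#' contingency tables stay well populated for small alignments.
#'
#' @return Character vector of length 21.
#' @export
mdmi_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' @rdname mdmi_alphabet
#' @export
gap_code <- function() 21L

#' Construct an encoded alignment
#'
#' @param mat Integer matrix, N sequences x L columns, entries indexing
#'   \code{alphabet} (1-based).
#' @param sequence_ids Character vector of N identifiers (generated if NULL).
#' @param alphabet Ordered symbol vector; defaults to [mdmi_alphabet()].
#' @param reference_index Optional row index of the structure-bearing
#'   sequence.
#' @return An object of class \code{encoded_alignment}.
#' @export
encoded_alignment <- function(mat, sequence_ids = NULL,
                              alphabet = mdmi_alphabet(),
                              reference_index = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("alignment error: need at least 2 sequences and 2 columns")
  if (anyNA(mat) || any(mat < 1L) || any(mat > length(alphabet)))
    stop("alignment error: matrix entries must index the alphabet")
  if (is.null(sequence_ids))
    sequence_ids <- paste0("seq", seq_len(nrow(mat)))
  if (length(sequence_ids) != nrow(mat))
    stop("alignment error: sequence_ids length must equal number of rows")
  if (!is.null(reference_index)) {
    reference_index <- as.integer(reference_index)
    stopifnot(reference_index >= 1L, reference_index <= nrow(mat))
  }
  structure(
    list(matrix = mat, alphabet = alphabet,
         sequence_ids = as.character(sequence_ids),
         reference_index = reference_index),
    class = "encoded_alignment")
}

#' @export
print.encoded_alignment <- function(x, ...) {
  cat(sprintf("encoded_alignment: %d sequences x %d columns, gap fraction %.3f\n",
              nrow(x$matrix), ncol(x$matrix), gap_fraction(x)))
  invisible(x)
}

#' @export
dim.encoded_alignment <- function(x) dim(x$matrix)

#' Fraction of gap-coded cells in an alignment
#' @param aln An \code{encoded_alignment}.
#' @return Numeric scalar in [0, 1].
#' @export
gap_fraction <- function(aln) {
  mean(aln$matrix == match("-", aln$alphabet))
}

encode_letters <- function(letters, alphabet = mdmi_alphabet()) {
  codes <- match(toupper(letters), alphabet)
  codes[is.na(codes)] <- match("-", alphabet)
  codes
}

decode_codes <- function(codes, alphabet = mdmi_alphabet()) {
  alphabet[codes]
}

#' Read an aligned FASTA or Stockholm file
#'
#' All records must have identical length. Letters outside the 20 standard
#' amino acids (including \code{"."}) are coded as gaps; matching is
#' case-insensitive.
#'
#' @param path File path.
#' @param format \code{"fasta"} or \code{"stockholm"}.
#' @return An [encoded_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  seqs <- switch(format,
    fasta = Biostrings::readBStringSet(path),
    stockholm = Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm")))
  if (length(seqs) == 0L)
    stop("input error: no sequences in ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment error: records have unequal lengths (",
         paste(unique(w), collapse = ", "), ")")
  chars <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  mat <- matrix(encode_letters(chars), nrow = nrow(chars))
  encoded_alignment(mat, sequence_ids = names(seqs))
}

#' Write an encoded alignment as aligned FASTA
#'
#' @param aln An \code{encoded_alignment}.
#' @param path Output file path (written atomically).
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(aln, path) {
  strings <- apply(aln$matrix, 1L, function(r)
    paste(decode_codes(r, aln$alphabet), collapse = ""))
  xs <- Biostrings::BStringSet(setNames(strings, aln$sequence_ids))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".fasta")
  Biostrings::writeXStringSet(xs, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Map alignment columns to structure residue numbers
#'
#' Walks the reference row of the alignment: its k-th non-gap column is
#' mapped to the k-th residue identifier. Only columns where the reference
#' sequence has a residue are mapped, so the mapping is injective.
#'
#' @param aln An \code{encoded_alignment}.
#' @param ref_row Row index of the reference (structure-bearing) sequence.
#' @param residue_numbers Integer vector of structure residue numbers, in
#'   sequence order; its length must equal the number of non-gap symbols in
#'   the reference row.
#' @param chain Chain identifier the residues belong to.
#' @return A \code{colstruct_map}: data.frame with columns \code{column}
#'   (alignment column, 1-based) and \code{residue}; attributes \code{chain}
#'   and \code{L} (alignment width).
#' @export
map_columns_to_structure <- function(aln, ref_row, residue_numbers,
                                     chain = "A") {
  stopifnot(inherits(aln, "encoded_alignment"))
  ref_row <- as.integer(ref_row)
  if (ref_row < 1L || ref_row > nrow(aln$matrix))
    stop("mapping error: ref_row out of range")
  nongap <- which(aln$matrix[ref_row, ] != match("-", aln$alphabet))
  if (length(nongap) == 0L) {
    warning("reference row is all gaps; empty column-structure map")
    residue_numbers <- integer(0)
  } else if (length(nongap) != length(residue_numbers)) {
    stop(sprintf(
      "mapping error: reference row has %d residues but %d residue numbers given",
      length(nongap), length(residue_numbers)))
  }
  out <- data.frame(column = nongap,
                    residue = as.integer(residue_numbers))
  attr(out, "chain") <- chain
  attr(out, "L") <- ncol(aln$matrix)
  class(out) <- c("colstruct_map", "data.frame")
  out
}

# residue number -> alignment column lookup (NA when unmapped)
residue_to_column <- function(colmap, residues) {
  colmap$column[match(residues, colmap$residue)]
}
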