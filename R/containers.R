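#' @useDynLib msaparam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# Residue alphabet accepted in input sequences: the 20 standard amino acids
# plus the IUPAC ambiguity codes B (Asx), Z (Glx), X (unknown).
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALLOWED <- c(AA_STANDARD, "X", "B", "Z")
GAP <- "-"

.check_residues <- function(x, ids, allow_gap = FALSE) {
  allowed <- if (allow_gap) c(AA_ALLOWED, GAP) else AA_ALLOWED
  for (i in seq_along(x)) {
    ch <- unique(strsplit(x[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(ch, allowed)
    if (length(bad) > 0L) {
      stop("record '", ids[[i]], "' contains unsupported letter(s): ",
           paste(bad, collapse = " "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a set of unaligned protein sequences
#'
#' A `SequenceSet` is the unit the parameter theory operates on: one protein
#' family of at least two ungapped sequences with unique identifiers.
#'
#' @param residues Character vector of sequences (upper-cased on input).
#' @param ids Sequence identifiers; defaults to `names(residues)`.
#' @return An object of class `SequenceSet`: a named character vector.
#' @examples
#' fam <- sequence_set(c(s1 = "ACDEFGHIK", s2 = "ACDEFGHIR"))
#' lengths <- nchar(fam)
#' @export
sequence_set <- function(residues, ids = names(residues)) {
  force(ids)
  residues <- toupper(as.character(residues))
  if (is.null(ids)) stop("sequence ids are required", call. = FALSE)
  ids <- as.character(ids)
  if (length(residues) < 2L) stop("a SequenceSet needs >= 2 sequences", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence(s): ", paste(ids[!nzchar(residues)], collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("[-.~]", residues))) {
    stop("gap characters found in unaligned input (use read_aligned_fasta for alignments)",
         call. = FALSE)
  }
  .check_residues(residues, ids)
  structure(stats::setNames(residues, ids), class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat("SequenceSet of", length(x), "sequences, lengths",
      min(nchar(x)), "-", max(nchar(x)), "\n")
  for (i in seq_along(x)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %-12s %s%s\n", names(x)[i],
                substr(s, 1, 50), if (nchar(s) > 50) "..." else ""))
  }
  invisible(x)
}

#' @export
`[.SequenceSet` <- function(x, i) {
  out <- unclass(x)[i]
  structure(out, class = "SequenceSet")
}

#' Construct a multiple sequence alignment
#'
#' Equal-length gapped rows over the amino-acid alphabet plus `-`. Rows keep
#' their input order; stripping gaps from the rows must recover a valid
#' [sequence_set()].
#'
#' @param rows Character vector of aligned rows (may contain `-`).
#' @param ids Row identifiers; defaults to `names(rows)`.
#' @return An object of class `Alignment`: a named character vector with
#'   attribute `L` (column count).
#' @examples
#' aln <- alignment(c(s1 = "AC-E", s2 = "ACDE"))
#' alignment_length(aln)
#' @export
alignment <- function(rows, ids = names(rows)) {
  force(ids)
  rows <- toupper(as.character(rows))
  if (is.null(ids)) stop("row ids are required", call. = FALSE)
  ids <- as.character(ids)
  if (length(rows) < 2L) stop("an Alignment needs >= 2 rows", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  L <- nchar(rows)
  if (any(L != L[1L]) ) {
    bad <- ids[L != L[1L]][1L]
    stop("ragged alignment: row '", bad, "' has length ", nchar(rows[L != L[1L]][1L]),
         ", expected ", L[1L], call. = FALSE)
  }
  if (L[1L] < 1L) stop("alignment must have >= 1 column", call. = FALSE)
  if (any(gsub("-", "", rows, fixed = TRUE) == "")) {
    stop("all-gap row(s): ",
         paste(ids[gsub("-", "", rows, fixed = TRUE) == ""], collapse = ", "),
         call. = FALSE)
  }
  .check_residues(rows, ids, allow_gap = TRUE)
  structure(stats::setNames(rows, ids), class = "Alignment", L = L[1L])
}

#' @rdname alignment
#' @param aln An `Alignment`.
#' @export
alignment_length <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  attr(aln, "L")
}

#' Strip gaps from an alignment
#'
#' @param aln An `Alignment`.
#' @return The underlying [sequence_set()] in row order.
#' @export
ungap <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  sequence_set(gsub("-", "", unclass(aln), fixed = TRUE), ids = names(aln))
}

#' @export
print.Alignment <- function(x, ...) {
  cat("Alignment:", length(x), "rows x", attr(x, "L"), "columns\n")
  for (i in seq_along(x)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %-12s %s%s\n", names(x)[i],
                substr(s, 1, 60), if (nchar(s) > 60) "..." else ""))
  }
  invisible(x)
}

# Split alignment rows into a k x L character matrix.
aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
}
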