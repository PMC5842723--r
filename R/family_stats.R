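# Statistics of an unaligned protein family. These feed every parameter
# formula: m (sequence count), len_max/len_min, mean pairwise identity
# (iden), the expected matched-pair count num_match and the per-sequence
# gap-count bound num_gap.

#' Pairwise identity of two unaligned sequences
#'
#' Globally aligns the two sequences with affine-gap dynamic programming and
#' returns the number of columns carrying identical residues divided by the
#' shorter sequence length.
#'
#' @param a,b Protein sequences (single strings).
#' @param matrix Substitution matrix used for the alignment; default
#'   BLOSUM62.
#' @param gop,gep Affine gap penalties for the identity alignment
#'   (defaults 10 and 1: a conventional, deterministic internal setting).
#' @return Fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACDE", "ACDE")  # 1
#' @export
pairwise_identity <- function(a, b, matrix = load_blosum("blosum62"),
                              gop = 10, gep = 1) {
  aln <- pairwise_affine_align(a, b, matrix, gop, gep)
  cm <- aln_char_matrix(aln)
  ident <- sum(cm[1L, ] == cm[2L, ] & cm[1L, ] != "-")
  len_min <- min(nchar(gsub("-", "", unclass(aln), fixed = TRUE)))
  ident / len_min
}

#' Family statistics of an unaligned sequence set
#'
#' Computes the inputs of the matrix-rationality test and the gap-penalty
#' estimators: sequence count `m`, longest/shortest lengths, mean pairwise
#' identity `iden`, the expected matched-residue pair count
#' `num_match = (m(m-1)/2) * len_min * iden`, and the per-sequence gap bound
#' `num_gap = floor(0.2 * len_max) + len_max - len_min`.
#'
#' @param seqs A [sequence_set()].
#' @param matrix,gop,gep Parameters of the identity alignments (see
#'   [pairwise_identity()]).
#' @param identity Optional known mean identity in \[0, 1\] (e.g. from a
#'   benchmark annotation); skips the all-pairs alignment when supplied.
#' @return A `FamilyStats` list: `m`, `len_max`, `len_min`, `iden`,
#'   `num_match`, `num_gap`.
#' @examples
#' fam <- sequence_set(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
#' family_summary(fam)
#' @export
family_summary <- function(seqs, matrix = load_blosum("blosum62"),
                           gop = 10, gep = 1, identity = NULL) {
  stopifnot(inherits(seqs, "SequenceSet"))
  m <- length(seqs)
  lens <- nchar(seqs)
  len_max <- max(lens)
  len_min <- min(lens)
  if (is.null(identity)) {
    pairs <- utils::combn(m, 2L)
    iden <- mean(apply(pairs, 2L, function(p) {
      pairwise_identity(seqs[p[1L]], seqs[p[2L]], matrix, gop, gep)
    }))
  } else {
    stopifnot(is.numeric(identity), identity >= 0, identity <= 1)
    iden <- identity
  }
  family_stats(m = m, len_max = len_max, len_min = len_min, iden = iden)
}

#' @rdname family_summary
#' @param m,len_max,len_min,iden Known family statistics, when building the
#'   record directly rather than from sequences.
#' @export
family_stats <- function(m, len_max, len_min, iden) {
  stopifnot(m >= 2, len_min >= 1, len_min <= len_max, iden >= 0, iden <= 1)
  structure(list(
    m = as.integer(m),
    len_max = as.integer(len_max),
    len_min = as.integer(len_min),
    iden = iden,
    num_match = (m * (m - 1) / 2) * len_min * iden,
    num_gap = floor(0.2 * len_max) + len_max - len_min
  ), class = "FamilyStats")
}

#' @export
print.FamilyStats <- function(x, ...) {
  cat(sprintf(
    "FamilyStats: m=%d len_max=%d len_min=%d iden=%.4f num_match=%.2f num_gap=%d\n",
    x$m, x$len_max, x$len_min, x$iden, x$num_match, as.integer(x$num_gap)))
  invisible(x)
}

#' Gap ratio of an alignment relative to the longest input sequence
#'
#' `(aln_len - len_max) / len_max`: how much the alignment stretched beyond
#' the longest unaligned sequence.
#'
#' @param aln_len Alignment length in columns.
#' @param len_max Length of the longest unaligned sequence.
#' @return Fraction >= 0.
#' @examples
#' gap_ratio(25, 21)  # 4/21
#' @export
gap_ratio <- function(aln_len, len_max) {
  stopifnot(len_max >= 1)
  if (aln_len < len_max) {
    stop("alignment length (", aln_len, ") below longest sequence length (",
         len_max, ")", call. = FALSE)
  }
  (aln_len - len_max) / len_max
}

#' Number of gaps inserted into one sequence by an alignment
#'
#' @param aln_len Alignment length in columns.
#' @param seq_len Ungapped length of the sequence.
#' @return `aln_len - seq_len`.
#' @examples
#' gaps_inserted(25, 21)  # 4
#' gaps_inserted(25, 7)   # 18
#' @export
gaps_inserted <- function(aln_len, seq_len) {
  stopifnot(seq_len >= 1)
  if (aln_len < seq_len) {
    stop("alignment length (", aln_len, ") below sequence length (",
         seq_len, ")", call. = FALSE)
  }
  aln_len - seq_len
}
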