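# The sum-of-pairs objective: total pairwise residue score over all columns
# minus affine gap penalties, plus the SPS metric for comparing a test
# alignment against a reference.

#' Score of one column-symbol pair
#'
#' Both residues: the matrix score. Residue against gap, or gap against gap:
#' zero (gaps are charged through the affine penalty term, never here).
#'
#' @param a,b Column symbols (residue letters or `-`).
#' @param matrix A `SubstitutionMatrix`.
#' @return A score.
#' @export
residue_cost <- function(a, b, matrix) {
  if (a == "-" || b == "-") return(0)
  matrix_score(matrix, a, b)
}

#' Decompose an alignment's gaps into openings and extensions
#'
#' Per row, each maximal run of `-` contributes one opening and
#' `run length - 1` extensions; totals are summed over rows. Terminal runs
#' count like internal ones.
#'
#' @param aln An [alignment()].
#' @return A `GapDecomposition` list: `n_gop`, `n_gep`.
#' @examples
#' count_gaps(alignment(c(a = "A--A", b = "AAAA")))  # 1 opening, 1 extension
#' @export
count_gaps <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  n_gop <- 0L; n_gep <- 0L
  for (row in unclass(aln)) {
    r <- rle(strsplit(row, "", fixed = TRUE)[[1]] == "-")
    runs <- r$lengths[r$values]
    n_gop <- n_gop + length(runs)
    n_gep <- n_gep + sum(runs - 1L)
  }
  structure(list(n_gop = n_gop, n_gep = as.integer(n_gep)),
            class = "GapDecomposition")
}

#' Sum-of-pairs score of an alignment
#'
#' `score = residue_total - penalty_total` where `residue_total` sums
#' [residue_cost()] over all columns and all row pairs, and
#' `penalty_total = n_gop * gop + n_gep * gep` from [count_gaps()].
#'
#' @param aln An [alignment()].
#' @param matrix A `SubstitutionMatrix`.
#' @param gop,gep Affine gap penalties (`gop > 0`, `gep >= 0`).
#' @return An `SPResult` list: `residue_total`, `penalty_total`, `score`.
#' @examples
#' aln <- alignment(c(a = "AC-E", b = "ACDE"))
#' sp_score(aln, load_blosum("blosum62"), gop = 10, gep = 1)
#' @export
sp_score <- function(aln, matrix, gop, gep) {
  stopifnot(inherits(aln, "Alignment"), inherits(matrix, "SubstitutionMatrix"),
            gop > 0, gep >= 0)
  cm <- aln_char_matrix(aln)
  letters_used <- setdiff(unique(as.vector(cm)), "-")
  miss <- setdiff(letters_used, rownames(matrix))
  if (length(miss) > 0L) {
    stop("letter(s) not in matrix ", attr(matrix, "name"), ": ",
         paste(miss, collapse = " "), call. = FALSE)
  }
  S <- unclass(matrix)
  residue_total <- 0
  for (j in seq_len(ncol(cm))) {
    col <- cm[, j]
    col <- col[col != "-"]
    if (length(col) < 2L) next
    counts <- table(col)
    v <- as.numeric(counts)
    letters_col <- names(counts)
    Ssub <- S[letters_col, letters_col, drop = FALSE]
    # sum over unordered pairs: (c' S c - sum_a c_a S_aa) / 2
    residue_total <- residue_total +
      (drop(t(v) %*% Ssub %*% v) - sum(v * diag(Ssub))) / 2
  }
  gd <- count_gaps(aln)
  penalty_total <- gd$n_gop * gop + gd$n_gep * gep
  structure(list(residue_total = residue_total,
                 penalty_total = penalty_total,
                 score = residue_total - penalty_total),
            class = "SPResult")
}

#' @export
print.SPResult <- function(x, ...) {
  cat(sprintf("SPResult: residue=%.2f penalty=%.2f score=%.2f\n",
              x$residue_total, x$penalty_total, x$score))
  invisible(x)
}

#' SPS: fraction of reference residue pairs recovered by a test alignment
#'
#' For every reference column and every row pair where both rows carry a
#' residue, that residue pair is a reference pair. SPS is the fraction of
#' reference pairs whose two residues also share a column in the test
#' alignment (the BAliBASE residue-pair recall convention). 1.0 means the
#' test reproduces every reference pairing.
#'
#' @param test,ref [alignment()]s over the same ids and the same ungapped
#'   sequences.
#' @return Fraction in \[0, 1\].
#' @examples
#' r <- alignment(c(a = "AC-E", b = "ACDE"))
#' sps(r, r)  # 1
#' @export
sps <- function(test, ref) {
  stopifnot(inherits(test, "Alignment"), inherits(ref, "Alignment"))
  if (!setequal(names(test), names(ref))) {
    stop("test and reference alignments have different sequence ids",
         call. = FALSE)
  }
  rows_t <- unclass(test)[names(ref)]
  ut <- unname(gsub("-", "", rows_t, fixed = TRUE))
  ur <- unname(c(gsub("-", "", unclass(ref), fixed = TRUE)))
  if (!identical(ut, ur)) {
    bad <- names(ref)[which(ut != ur)[1L]]
    stop("ungapped sequences differ between test and reference (row '",
         bad, "')", call. = FALSE)
  }
  cmr <- aln_char_matrix(ref)
  cmt <- do.call(rbind, strsplit(rows_t, "", fixed = TRUE))
  k <- nrow(cmr)
  # residue index -> column index maps
  colmap <- function(cm) {
    lapply(seq_len(nrow(cm)), function(i) which(cm[i, ] != "-"))
  }
  # map_t[[i]][p] = test column of residue p of sequence i
  map_t <- colmap(cmt)
  # per-row, per-ref-column residue ordinal (NA at gaps)
  ord_r <- lapply(seq_len(k), function(i) {
    res <- cmr[i, ] != "-"
    out <- rep(NA_integer_, ncol(cmr))
    out[res] <- seq_len(sum(res))
    out
  })
  total <- 0L; hit <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      both <- !is.na(ord_r[[i]]) & !is.na(ord_r[[j]])
      p <- ord_r[[i]][both]; q <- ord_r[[j]][both]
      total <- total + length(p)
      if (length(p) > 0L) {
        hit <- hit + sum(map_t[[i]][p] == map_t[[j]][q])
      }
    }
  }
  if (total == 0L) {
    stop("reference alignment has no residue pairs to score", call. = FALSE)
  }
  hit / total
}
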