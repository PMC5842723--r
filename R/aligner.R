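# A small progressive multiple aligner: Gotoh affine pairwise alignment,
# UPGMA guide tree on 1 - pairwise identity, and profile-profile merges.
# It optimises the same objective sp_score() measures: a gap run of length R
# costs gop + (R-1)*gep, terminal runs included.

.as_seq_pair <- function(a, b) {
  ida <- if (!is.null(names(a)) && nzchar(names(a)[1])) names(a)[1] else "seq1"
  idb <- if (!is.null(names(b)) && nzchar(names(b)[1])) names(b)[1] else "seq2"
  if (identical(ida, idb)) idb <- paste0(idb, ".2")
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  .check_residues(c(a, b), c(ida, idb))
  list(a = a, b = b, ida = ida, idb = idb)
}

.check_affine_params <- function(gop, gep) {
  stopifnot(is.numeric(gop), is.numeric(gep), gep >= 0)
  if (gop < gep) {
    warning("gap-open penalty (", gop, ") below gap-extension penalty (", gep,
            "); the affine model expects GOP > GEP", call. = FALSE)
  }
}

#' Optimal global pairwise alignment with affine gap penalties
#'
#' Three-state Gotoh dynamic programming maximising
#' `sum matrix(a_i, b_j) - sum over gap runs (gop + (R - 1) * gep)`.
#' Ties are broken deterministically (match over gap in the first sequence
#' over gap in the second).
#'
#' @param a,b Protein sequences (single strings; names become row ids).
#' @param matrix A `SubstitutionMatrix`, e.g. [load_blosum()].
#' @param gop,gep Gap-open and gap-extension penalties (positive scores).
#' @return An [alignment()] of two rows; attribute `score` holds the optimal
#'   objective value.
#' @examples
#' aln <- pairwise_affine_align("HEAGAWGHEE", "PAWHEAE", load_blosum("blosum62"), 10, 1)
#' attr(aln, "score")
#' @export
pairwise_affine_align <- function(a, b, matrix, gop, gep) {
  stopifnot(inherits(matrix, "SubstitutionMatrix"))
  .check_affine_params(gop, gep)
  p <- .as_seq_pair(a, b)
  ca <- strsplit(p$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(p$b, "", fixed = TRUE)[[1]]
  miss <- setdiff(unique(c(ca, cb)), rownames(matrix))
  if (length(miss) > 0L) {
    stop("letter(s) not in matrix ", attr(matrix, "name"), ": ",
         paste(miss, collapse = " "), call. = FALSE)
  }
  cost <- unclass(matrix)[ca, cb, drop = FALSE]
  res <- .gotoh_align(cost, gop, gep, gop, gep)
  row_a <- ifelse(res$a == 0L, "-", ca[pmax(res$a, 1L)])
  row_b <- ifelse(res$b == 0L, "-", cb[pmax(res$b, 1L)])
  out <- alignment(stats::setNames(c(paste(row_a, collapse = ""),
                                     paste(row_b, collapse = "")),
                                   c(p$ida, p$idb)))
  attr(out, "score") <- res$score
  out
}

#' UPGMA guide tree from pairwise identities
#'
#' Agglomerates sequences by average linkage on the distance
#' `1 - pairwise_identity`. Ties in the minimum distance are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest member id), so the tree is deterministic.
#'
#' @param seqs A [sequence_set()].
#' @param matrix,gop,gep Parameters for the identity alignments.
#' @return A `GuideTree`: list with `merges` (list of steps, each holding the
#'   member ids of the two clusters joined and the linkage height) and
#'   `labels`.
#' @export
build_guide_tree <- function(seqs, matrix, gop, gep) {
  stopifnot(inherits(seqs, "SequenceSet"))
  ids <- names(seqs)
  m <- length(seqs)
  D <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      d <- 1 - pairwise_identity(seqs[i], seqs[j], matrix, gop, gep)
      D[i, j] <- D[j, i] <- d
    }
  }
  upgma_merge(D)
}

# Average-linkage agglomeration with an explicit lexicographic tie rule.
upgma_merge <- function(D) {
  ids <- rownames(D)
  clusters <- as.list(ids)           # member ids per active cluster
  sizes <- rep(1L, length(ids))
  labels <- ids                      # smallest member id per cluster
  active <- rep(TRUE, length(ids))
  merges <- list()
  Dw <- D
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        lab <- sort(c(labels[i], labels[j]))
        cand <- list(i = i, j = j, d = Dw[i, j], lab = lab)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (cand$lab[1] < best$lab[1] ||
              (cand$lab[1] == best$lab[1] && cand$lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merges[[length(merges) + 1L]] <- list(
      left = clusters[[i]], right = clusters[[j]], height = best$d / 2)
    # UPGMA update: size-weighted average distance to the new cluster
    for (k in which(active)) {
      if (k == i || k == j) next
      Dw[i, k] <- Dw[k, i] <-
        (sizes[i] * Dw[i, k] + sizes[j] * Dw[j, k]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    labels[i] <- min(labels[i], labels[j])
    active[j] <- FALSE
  }
  structure(list(merges = merges, labels = ids), class = "GuideTree")
}

#' @export
print.GuideTree <- function(x, ...) {
  cat("GuideTree over", length(x$labels), "sequences\n")
  for (s in x$merges) {
    cat(sprintf("  (%s) + (%s) at height %.4f\n",
                paste(s$left, collapse = ","),
                paste(s$right, collapse = ","), s$height))
  }
  invisible(x)
}

# Column frequency profile of a set of aligned rows: |alphabet| x L matrix,
# columns sum to 1 with gaps carrying the residual frequency (gap frequency
# contributes zero score, matching the SP gap convention).
profile_freqs <- function(rows, alphabet) {
  cm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  k <- nrow(cm); L <- ncol(cm)
  F <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (j in seq_len(L)) {
    tb <- table(cm[, j])
    tb <- tb[names(tb) != "-"]
    if (length(tb) > 0L) F[names(tb), j] <- as.numeric(tb) / k
  }
  F
}

# Merge two blocks of aligned rows along a Gotoh path over profile scores.
# Costs are kept on the sum-of-pairs scale of the final alignment: residue
# scores sum over all k1 x k2 cross-row pairs, and a gap column inserted
# into a block opens a run in each of its rows, so penalties scale with the
# receiving block's row count.
.merge_blocks <- function(rows1, rows2, matrix, gop, gep) {
  alphabet <- rownames(matrix)
  k1 <- length(rows1); k2 <- length(rows2)
  F1 <- profile_freqs(rows1, alphabet)
  F2 <- profile_freqs(rows2, alphabet)
  cost <- (k1 * k2) * (t(F1) %*% unclass(matrix) %*% F2)
  res <- .gotoh_align(cost, k1 * gop, k1 * gep, k2 * gop, k2 * gep)
  c1 <- do.call(rbind, strsplit(rows1, "", fixed = TRUE))
  c2 <- do.call(rbind, strsplit(rows2, "", fixed = TRUE))
  n_out <- length(res$a)
  out1 <- matrix("-", nrow(c1), n_out)
  out2 <- matrix("-", nrow(c2), n_out)
  sel1 <- res$a != 0L
  sel2 <- res$b != 0L
  out1[, sel1] <- c1[, res$a[sel1], drop = FALSE]
  out2[, sel2] <- c2[, res$b[sel2], drop = FALSE]
  c(apply(out1, 1L, paste, collapse = ""),
    apply(out2, 1L, paste, collapse = ""))
}

#' Progressive multiple alignment
#'
#' Aligns profiles along a UPGMA guide tree ("once a gap, always a gap").
#' Profile-profile column scores are the expected residue score under the
#' product of column frequencies, gaps contributing zero. With two sequences
#' this reduces to [pairwise_affine_align()]. Deterministic for identical
#' inputs.
#'
#' @param seqs A [sequence_set()].
#' @param matrix A `SubstitutionMatrix`.
#' @param gop,gep Affine gap penalties.
#' @param guide_tree Optional precomputed [build_guide_tree()] result.
#' @return An [alignment()] whose rows, after gap removal, equal `seqs`
#'   (rows in input order).
#' @export
progressive_align <- function(seqs, matrix, gop, gep, guide_tree = NULL) {
  stopifnot(inherits(seqs, "SequenceSet"), inherits(matrix, "SubstitutionMatrix"))
  .check_affine_params(gop, gep)
  if (length(seqs) == 2L) {
    out <- pairwise_affine_align(seqs[1], seqs[2], matrix, gop, gep)
    attr(out, "score") <- NULL
    return(out)
  }
  if (is.null(guide_tree)) {
    guide_tree <- build_guide_tree(seqs, matrix, gop, gep)
  }
  blocks <- lapply(names(seqs), function(id) stats::setNames(unclass(seqs)[id], id))
  names(blocks) <- names(seqs)
  find_block <- function(id) which(vapply(blocks, function(b) id %in% names(b), logical(1)))
  for (step in guide_tree$merges) {
    bi <- find_block(step$left[1L])
    bj <- find_block(step$right[1L])
    rows1 <- blocks[[bi]]; rows2 <- blocks[[bj]]
    merged <- .merge_blocks(rows1, rows2, matrix, gop, gep)
    names(merged) <- c(names(rows1), names(rows2))
    blocks[[bi]] <- merged
    blocks[[bj]] <- NULL
  }
  rows <- blocks[[1L]][names(seqs)]
  alignment(rows)
}
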