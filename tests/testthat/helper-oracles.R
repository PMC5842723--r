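# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (exhaustive recursion, triple loops, set intersection)
# and share no code with the package internals they check.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# NCBI-style matrix text for a toy matrix: diag d, off-diagonal o.
toy_matrix <- function(d = 5, o = -1) {
  rows <- vapply(seq_along(AA20), function(i) {
    vals <- rep(o, length(AA20)); vals[i] <- d
    paste(AA20[i], paste(vals, collapse = " "))
  }, character(1))
  parse_score_matrix(c(paste(AA20, collapse = " "), rows), name = "toy")
}

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random gapped alignment over k rows and L columns (no all-gap rows/ragged)
random_alignment <- function(k = 3, L = 12, gap_p = 0.25, alphabet = AA20) {
  repeat {
    rows <- vapply(seq_len(k), function(i) {
      ch <- sample(alphabet, L, replace = TRUE)
      ch[stats::runif(L) < gap_p] <- "-"
      paste(ch, collapse = "")
    }, character(1))
    if (all(gsub("-", "", rows) != "")) {
      return(alignment(stats::setNames(rows, paste0("r", seq_len(k)))))
    }
  }
}

# Exhaustive global affine alignment: recursion over every monotone path,
# charging gop for the first gap of a run and gep for each extension.
brute_affine_score <- function(a, b, S, gop, gep) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, S[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(ca)) {  # gap in b
      pen <- if (last == "B") gep else gop
      best <- max(best, -pen + rec(i + 1, j, "B"))
    }
    if (j <= length(cb)) {  # gap in a
      pen <- if (last == "A") gep else gop
      best <- max(best, -pen + rec(i, j + 1, "A"))
    }
    best
  }
  rec(1, 1, "M")
}

# Naive SP score of an alignment: triple loop, runs found by scanning.
naive_sp_score <- function(aln, S, gop, gep) {
  rows <- strsplit(unclass(aln), "", fixed = TRUE)
  k <- length(rows); L <- length(rows[[1]])
  res <- 0
  for (h in seq_len(L)) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        x <- rows[[i]][h]; y <- rows[[j]][h]
        if (x != "-" && y != "-") res <- res + S[x, y]
      }
    }
  }
  pen <- 0
  for (i in seq_len(k)) {
    in_run <- FALSE
    for (h in seq_len(L)) {
      if (rows[[i]][h] == "-") {
        pen <- pen + if (in_run) gep else gop
        in_run <- TRUE
      } else in_run <- FALSE
    }
  }
  list(residue = res, penalty = pen, score = res - pen)
}

# Set-based SPS oracle: reference residue pairs as strings, intersected
# with the test alignment's pairs.
naive_sps <- function(test, ref) {
  pair_set <- function(aln) {
    rows <- strsplit(unclass(aln)[sort(names(aln))], "", fixed = TRUE)
    k <- length(rows); L <- length(rows[[1]])
    ord <- lapply(rows, function(r) cumsum(r != "-"))
    out <- character(0)
    for (h in seq_len(L)) {
      for (i in seq_len(k - 1)) {
        for (j in seq(i + 1, k)) {
          if (rows[[i]][h] != "-" && rows[[j]][h] != "-") {
            out <- c(out, paste(i, ord[[i]][h], j, ord[[j]][h], sep = ":"))
          }
        }
      }
    }
    out
  }
  rp <- pair_set(ref)
  length(intersect(rp, pair_set(test))) / length(rp)
}

# Independent evaluations of the matrix-rationality threshold and the GOP
# upper bound, re-typed from their closed forms with different factoring.
oracle_rationality_calc <- function(m, num_gap, num_match, sab, alpha, beta) {
  coef <- (alpha * (m - 2) - m) / (1 - m)
  coef / (2 * beta) * (num_gap / num_match) + sab / beta
}

oracle_gop_bound <- function(m, num_gap, num_match, saa, sab,
                             lambda, n, alpha, beta) {
  termA <- (alpha * (m - 2) - m) * ((m - 1) / 2) * num_gap * sab
  termB <- num_match * (beta * saa - sab)
  (termA + termB) * n * lambda / (m * (n + lambda - 1) * num_gap)
}

random_family_stats <- function() {
  m <- sample(2:25, 1)
  len_min <- sample(20:200, 1)
  len_max <- len_min + sample(0:100, 1)
  iden <- stats::runif(1, 0.05, 1)
  family_stats(m = m, len_max = len_max, len_min = len_min, iden = iden)
}
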