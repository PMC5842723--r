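# The core parameter theory: characterise a substitution matrix by its mean
# matched and mismatched scores, test whether the matrix is rational for a
# family, bound the gap-open penalty from above, and turn the bound into
# concrete GOP/GEP estimates via weight coefficients.

#' Weight coefficients of the parameter formulas
#'
#' `lambda` relates the per-sequence gap count to the number of gap openings
#' (each run of gaps averages `lambda` characters), `n` fixes the ratio
#' GOP = n * GEP, `omega` in (0, 1) scales the GOP upper bound into the
#' estimate, and `alpha`/`beta` down-weight the mismatch and match terms of
#' the score model. Defaults `lambda = 3`, `alpha = 0.2`, `beta = 0.9` are
#' the calibrated values shared by all sequence classes; `omega` and `n`
#' vary by class (see [select_preset()]).
#'
#' @param lambda,n Positive integers.
#' @param omega Weight in (0, 1).
#' @param alpha,beta Positive weights.
#' @return A `Weights` list.
#' @export
msa_weights <- function(lambda = 3, n = 5, omega = 0.05, alpha = 0.2, beta = 0.9) {
  stopifnot(lambda >= 1, lambda == round(lambda),
            n >= 1, n == round(n),
            omega > 0, omega < 1,
            alpha > 0, beta > 0)
  structure(list(lambda = as.integer(lambda), n = as.integer(n),
                 omega = omega, alpha = alpha, beta = beta),
            class = "Weights")
}

#' @export
print.Weights <- function(x, ...) {
  cat(sprintf("Weights: lambda=%d n=%d omega=%.3f alpha=%.2f beta=%.2f\n",
              x$lambda, x$n, x$omega, x$alpha, x$beta))
  invisible(x)
}

#' Mean matched and mismatched scores of a substitution matrix
#'
#' Reduces a matrix to two representative numbers: `mean_saa`, the
#' arithmetic mean of the 20 standard-amino-acid diagonal entries, and
#' `mean_sab`, the mean of the 190 strict-upper-triangle entries. Ambiguity
#' codes (B, Z, X) and the stop column are excluded.
#'
#' @param matrix A `SubstitutionMatrix`.
#' @return A `MatrixStats` list: `mean_saa`, `mean_sab`.
#' @examples
#' matrix_means(load_blosum("blosum62"))
#' @export
matrix_means <- function(matrix) {
  stopifnot(inherits(matrix, "SubstitutionMatrix"))
  core <- unclass(matrix)[AA_STANDARD, AA_STANDARD]
  structure(list(
    mean_saa = mean(diag(core)),
    mean_sab = mean(core[upper.tri(core)])
  ), class = "MatrixStats")
}

#' @export
print.MatrixStats <- function(x, ...) {
  cat(sprintf("MatrixStats: mean(Saa)=%.4f mean(Sab)=%.4f\n",
              x$mean_saa, x$mean_sab))
  invisible(x)
}

#' Matrix-rationality test for a family
#'
#' A matrix is rational for a family when its mean matched score (the
#' reference value) is at least the calculated value
#' \deqn{calc = \frac{\alpha m - 2\alpha - m}{(1 - m)\, 2\beta} \cdot
#'       \frac{num\_gap}{num\_match} + \frac{1}{\beta}\, \overline{S_{ab}},}
#' i.e. the worst admissible alignment still scores no worse than leaving
#' the family unaligned.
#'
#' @param stats A `FamilyStats` (see [family_summary()]).
#' @param mstats A `MatrixStats` (see [matrix_means()]).
#' @param w A `Weights` (see [msa_weights()]).
#' @return A `MatrixCheck` list: `reference` (mean matched score), `calc`
#'   and `passed` (`reference >= calc`).
#' @export
check_matrix <- function(stats, mstats, w = msa_weights()) {
  stopifnot(inherits(stats, "FamilyStats"), inherits(mstats, "MatrixStats"),
            inherits(w, "Weights"))
  if (stats$num_match <= 0) {
    stop("num_match is 0 (mean identity 0); supply an identity override to ",
         "family_summary() before testing the matrix", call. = FALSE)
  }
  m <- stats$m
  calc <- ((w$alpha * m - 2 * w$alpha - m) / ((1 - m) * 2 * w$beta)) *
    (stats$num_gap / stats$num_match) +
    mstats$mean_sab / w$beta
  structure(list(reference = mstats$mean_saa, calc = calc,
                 passed = mstats$mean_saa >= calc),
            class = "MatrixCheck")
}

#' @export
print.MatrixCheck <- function(x, ...) {
  cat(sprintf("MatrixCheck: reference=%.4f calc=%.4f -> %s\n",
              x$reference, x$calc, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Upper bound on the gap-open penalty
#'
#' The largest GOP for which the worst admissible alignment of the family
#' still scores at least the unaligned family:
#' \deqn{GOP \le \Big[\frac{(\alpha m - 2\alpha - m)(m-1)}{2}\,
#'   num\_gap\, \overline{S_{ab}} +
#'   num\_match\,(\beta \overline{S_{aa}} - \overline{S_{ab}})\Big]
#'   \cdot \frac{n\lambda}{m (n + \lambda - 1)\, num\_gap}.}
#'
#' @inheritParams check_matrix
#' @return The bound (a score).
#' @export
gop_upper_bound <- function(stats, mstats, w = msa_weights()) {
  stopifnot(inherits(stats, "FamilyStats"), inherits(mstats, "MatrixStats"),
            inherits(w, "Weights"))
  if (stats$num_gap <= 0) {
    stop("num_gap is 0: equal-length family needs no gap penalty bound",
         call. = FALSE)
  }
  if (stats$num_match <= 0) {
    stop("num_match is 0 (mean identity 0); supply an identity override",
         call. = FALSE)
  }
  m <- stats$m
  bracket <- (w$alpha * m - 2 * w$alpha - m) * (m - 1) / 2 *
    stats$num_gap * mstats$mean_sab +
    stats$num_match * (w$beta * mstats$mean_saa - mstats$mean_sab)
  bracket * (w$n * w$lambda) / (m * (w$n + w$lambda - 1) * stats$num_gap)
}

#' Estimate GOP and GEP for a family
#'
#' `GOP = omega * upper_bound` and `GEP = GOP / n`. A non-positive upper
#' bound (degenerate family statistics) is an error, never silently clamped.
#'
#' @param stats A `FamilyStats`.
#' @param matrix A `SubstitutionMatrix`.
#' @param w A `Weights`.
#' @return A `ParamEstimate` list: `gop`, `gep`, `upper_bound`,
#'   `matrix_name`, `weights`, `stats`.
#' @examples
#' st <- family_stats(m = 4, len_max = 120, len_min = 100, iden = 0.4)
#' estimate_gop_gep(st, load_blosum("blosum45"), msa_weights(omega = 0.05, n = 5))
#' @export
estimate_gop_gep <- function(stats, matrix, w = msa_weights()) {
  stopifnot(inherits(matrix, "SubstitutionMatrix"))
  mstats <- matrix_means(matrix)
  ub <- gop_upper_bound(stats, mstats, w)
  if (ub <= 0) {
    stop(sprintf(
      paste0("gap-penalty formula yields non-positive GOP bound (%.4f) for ",
             "m=%d num_gap=%d num_match=%.2f mean_saa=%.3f mean_sab=%.3f; ",
             "check the family statistics or fall back to defaults"),
      ub, stats$m, as.integer(stats$num_gap), stats$num_match,
      mstats$mean_saa, mstats$mean_sab), call. = FALSE)
  }
  structure(list(gop = w$omega * ub, gep = w$omega * ub / w$n,
                 upper_bound = ub, matrix_name = attr(matrix, "name"),
                 weights = w, stats = stats),
            class = "ParamEstimate")
}

#' @export
print.ParamEstimate <- function(x, ...) {
  cat(sprintf("ParamEstimate: GOP=%.4f GEP=%.4f (upper bound %.4f, matrix %s)\n",
              x$gop, x$gep, x$upper_bound, x$matrix_name))
  invisible(x)
}

#' Calibrated weight presets by sequence class
#'
#' Returns the calibrated `omega`, `n` and matrix for the family's class,
#' keyed on sequence count `m` and longest length `len_max`:
#' \itemize{
#'   \item m in 4-5, len_max < 100: omega 0.03, n 5, BLOSUM45
#'   \item m in 4-5, 100 <= len_max <= 300: omega 0.05, n 5, BLOSUM45
#'   \item m in 4-5, len_max > 300: omega 0.08, n 10, BLOSUM62
#'   \item m in 14-19: omega 0.02, n 10, BLOSUM45
#'   \item m >= 20: omega 0.02, n 10, BLOSUM45
#' }
#' Always `lambda = 3`, `alpha = 0.2`, `beta = 0.9`. Counts outside the
#' calibrated classes (m of 2-3 or 6-13) map to the nearest small-family
#' rows and are flagged `extrapolated`.
#'
#' @param stats A `FamilyStats`.
#' @return A list: `weights` (`Weights`), `matrix_name`, `class_label`,
#'   `extrapolated`.
#' @examples
#' select_preset(family_stats(m = 4, len_max = 150, len_min = 120, iden = 0.3))
#' @export
select_preset <- function(stats) {
  stopifnot(inherits(stats, "FamilyStats"))
  m <- stats$m; len <- stats$len_max
  extrapolated <- FALSE
  if (m <= 13) {
    extrapolated <- !(m %in% 4:5)
    if (len < 100) {
      omega <- 0.03; n <- 5L; mat <- "BLOSUM45"; lab <- "small family, short (<100)"
    } else if (len <= 300) {
      omega <- 0.05; n <- 5L; mat <- "BLOSUM45"; lab <- "small family, medium (100-300)"
    } else {
      omega <- 0.08; n <- 10L; mat <- "BLOSUM62"; lab <- "small family, long (>300)"
    }
  } else if (m <= 19) {
    omega <- 0.02; n <- 10L; mat <- "BLOSUM45"; lab <- "medium family (14-19)"
  } else {
    omega <- 0.02; n <- 10L; mat <- "BLOSUM45"; lab <- "large family (>=20)"
  }
  list(weights = msa_weights(lambda = 3, n = n, omega = omega,
                             alpha = 0.2, beta = 0.9),
       matrix_name = mat, class_label = lab, extrapolated = extrapolated)
}

#' One-call parameter choice for a family
#'
#' Convenience wrapper: family statistics, preset selection and GOP/GEP
#' estimation in one step. Used by the aligner's auto-parameter mode.
#'
#' @param seqs A [sequence_set()].
#' @param identity Optional known mean identity (see [family_summary()]).
#' @return A `ParamEstimate` with a `preset` attribute.
#' @export
auto_parameters <- function(seqs, identity = NULL) {
  stats <- family_summary(seqs, identity = identity)
  preset <- select_preset(stats)
  est <- estimate_gop_gep(stats, load_blosum(preset$matrix_name), preset$weights)
  attr(est, "preset") <- preset
  est
}
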