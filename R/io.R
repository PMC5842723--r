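# File formats: FASTA (unaligned and aligned), GCG MSF (read-only), and
# NCBI/EMBOSS substitution-matrix text. FASTA goes through Biostrings; MSF
# through seqinr; both are normalised and re-validated against the package's
# container invariants afterwards.

.fasta_ids <- function(xss) {
  # first whitespace-delimited token of the header line
  sub("\\s.*$", "", names(xss))
}

#' Read unaligned protein sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [sequence_set()]. Residues are upper-cased; ids are the first
#'   whitespace-delimited token of each header.
#' @details Duplicate ids, empty sequences and gap characters are errors; an
#'   aligned file should be read with [read_aligned_fasta()] instead.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  xss <- Biostrings::readBStringSet(path)
  if (length(xss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  sequence_set(as.character(xss), ids = .fasta_ids(xss))
}

#' Read an alignment from gapped FASTA
#'
#' Rows must all have the same length. The `.` gap dialect is normalised to
#' `-` on input.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [alignment()].
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  xss <- Biostrings::readBStringSet(path)
  if (length(xss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  rows <- gsub(".", "-", as.character(xss), fixed = TRUE)
  alignment(rows, ids = .fasta_ids(xss))
}

#' Write sequences or an alignment to FASTA
#'
#' @param x A `SequenceSet` or `Alignment`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "SequenceSet") || inherits(x, "Alignment"))
  xss <- Biostrings::BStringSet(stats::setNames(unclass(x), names(x)))
  Biostrings::writeXStringSet(xss, path, width = width)
  invisible(path)
}

#' Read a GCG MSF alignment
#'
#' Reads the interleaved MSF format used by BAliBASE-style reference
#' alignments. Gap dialects `.` and `~` are normalised to `-`.
#'
#' @param path Path to an MSF file.
#' @return An [alignment()] with the same contract as [read_aligned_fasta()].
#' @export
read_msf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  hdr <- grep("MSF:", txt, fixed = TRUE, value = TRUE)
  if (length(hdr) == 0L || !any(grepl("\\.\\.\\s*$", hdr))) {
    stop("not a GCG MSF file (missing 'MSF: ... ..' header sentinel): ", path,
         call. = FALSE)
  }
  a <- seqinr::read.alignment(path, format = "msf")
  rows <- toupper(unlist(a$seq, use.names = FALSE))
  rows <- gsub("[.~]", "-", rows)
  alignment(rows, ids = a$nam)
}

#' Parse an NCBI/EMBOSS substitution-matrix text
#'
#' Parses the whitespace-separated matrix layout used by the NCBI BLOSUM
#' distribution files (header row of letters, one labelled row per letter,
#' `#` comments). The result is an exactly symmetric integer lookup.
#'
#' @param text Matrix text: a single string or a character vector of lines.
#' @param name Name recorded on the matrix (e.g. `"BLOSUM62"`).
#' @return A `SubstitutionMatrix`: an integer matrix with residue dimnames
#'   and a `name` attribute.
#' @examples
#' m <- load_blosum("blosum62")
#' m["A", "A"]  # 4
#' @export
parse_score_matrix <- function(text, name = "custom") {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]
  if (length(text) < 2L) stop("matrix text too short", call. = FALSE)
  header <- strsplit(text[1L], "\\s+")[[1]]
  if (!all(nchar(header) == 1L)) {
    stop("matrix header must be single residue letters", call. = FALSE)
  }
  n <- length(header)
  m <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (ln in text[-1L]) {
    tok <- strsplit(ln, "\\s+")[[1]]
    row <- tok[1L]
    if (!(row %in% header)) stop("unexpected row label '", row, "'", call. = FALSE)
    vals <- suppressWarnings(as.numeric(tok[-1L]))
    if (length(vals) != n || anyNA(vals)) {
      stop("row '", row, "': expected ", n, " numeric cells", call. = FALSE)
    }
    if (any(vals != round(vals))) {
      stop("row '", row, "': non-integer score cell", call. = FALSE)
    }
    m[row, ] <- as.integer(vals)
  }
  if (anyNA(m)) {
    missing_rows <- rownames(m)[apply(m, 1L, anyNA)]
    stop("missing row(s) for letter(s): ", paste(missing_rows, collapse = " "),
         call. = FALSE)
  }
  if (!identical(m, t(m))) stop("matrix is not symmetric", call. = FALSE)
  miss <- setdiff(AA_STANDARD, header)
  if (length(miss) > 0L) {
    stop("matrix lacks standard amino acid(s): ", paste(miss, collapse = " "),
         call. = FALSE)
  }
  structure(m, class = c("SubstitutionMatrix", "matrix", "array"), name = name)
}

#' @rdname parse_score_matrix
#' @param path Path to a matrix text file.
#' @export
read_score_matrix <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_score_matrix(readLines(path, warn = FALSE), name = name)
}

#' Load a bundled BLOSUM matrix
#'
#' BLOSUM30, BLOSUM45 and BLOSUM62 (the standard NCBI half-bit matrices) are
#' bundled as plain-text fixtures.
#'
#' @param name `"blosum30"`, `"blosum45"` or `"blosum62"` (case-insensitive).
#' @return A `SubstitutionMatrix`.
#' @export
load_blosum <- function(name = c("blosum62", "blosum45", "blosum30")) {
  name <- toupper(match.arg(tolower(name[1L]), c("blosum62", "blosum45", "blosum30")))
  path <- system.file("extdata", "matrices", paste0(name, ".txt"),
                      package = "msaparam", mustWork = TRUE)
  read_score_matrix(path, name = name)
}

#' @export
print.SubstitutionMatrix <- function(x, ...) {
  cat("SubstitutionMatrix", attr(x, "name"), "-",
      nrow(x), "x", ncol(x), "letters\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Look up a residue-pair score
#'
#' @param matrix A `SubstitutionMatrix`.
#' @param a,b Single residue letters.
#' @return Integer score. Unknown letters are an error, never a fabricated
#'   score.
#' @export
matrix_score <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "SubstitutionMatrix"))
  for (ch in c(a, b)) {
    if (!(ch %in% rownames(matrix))) {
      stop("letter '", ch, "' not in matrix ", attr(matrix, "name"), call. = FALSE)
    }
  }
  unclass(matrix)[a, b]
}
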