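#' Scoring scheme for local alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties.  A gap
#' run of length \eqn{L} costs \code{gapOpening + (L - 1) * gapExtension}:
#' the first gap column pays the opening penalty only.  Penalties are stored
#' as magnitudes (non-negative numbers that are subtracted from the score).
#'
#' The default matrix is BLOSUM62, whose alphabet happens to contain the
#' nucleotide letters A, C, G and T (with diagonal scores 4, 9, 6 and 5), so
#' it is usable for DNA; [nucleotideScheme()] builds a conventional
#' match/mismatch matrix instead.  Regardless of the matrix, the aligner
#' scores the placeholder residue \code{N} as 0 against every symbol
#' (neutral), so a rare undetermined base neither rewards nor penalises an
#' alignment.
#'
#' @slot matrix symmetric numeric matrix with single-character dimnames.
#' @slot gapOpening non-negative penalty for the first column of a gap.
#' @slot gapExtension non-negative penalty for each further gap column;
#'   must not exceed \code{gapOpening}.
#'
#' @seealso [blosum62Scheme()], [nucleotideScheme()],
#'   [loadSubstitutionMatrix()]
#' @export
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpening = "numeric",
                 gapExtension = "numeric"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  msg <- character()
  if (!is.numeric(m) || nrow(m) != ncol(m))
    msg <- c(msg, "matrix must be a square numeric matrix")
  else {
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)) ||
        any(nchar(rownames(m)) != 1L))
      msg <- c(msg, "matrix must have identical single-character row/col names")
    else if (!isTRUE(all.equal(m, t(m))))
      msg <- c(msg, "matrix must be symmetric")
  }
  if (length(object@gapOpening) != 1L || is.na(object@gapOpening) ||
      length(object@gapExtension) != 1L || is.na(object@gapExtension) ||
      object@gapExtension < 0 || object@gapOpening < object@gapExtension)
    msg <- c(msg, "penalties must satisfy gapOpening >= gapExtension >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a scoring scheme
#'
#' @param matrix symmetric numeric substitution matrix with single-character
#'   dimnames, e.g. from [loadSubstitutionMatrix()].
#' @param gapOpening,gapExtension affine gap penalty magnitudes; a gap of
#'   length L costs \code{gapOpening + (L - 1) * gapExtension}.
#' @return A [ScoringScheme-class] object.
#' @examples
#' sch <- ScoringScheme(nucleotideMatrix(), gapOpening = 10, gapExtension = 0.5)
#' @export
ScoringScheme <- function(matrix, gapOpening = 10, gapExtension = 0.5) {
  new("ScoringScheme", matrix = matrix,
      gapOpening = as.numeric(gapOpening),
      gapExtension = as.numeric(gapExtension))
}

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme with", nrow(object@matrix), "symbols (",
      paste(head(rownames(object@matrix), 8), collapse = ""),
      if (nrow(object@matrix) > 8) "..." else "", ")\n", sep = "")
  cat("  gap opening:", object@gapOpening,
      " gap extension:", object@gapExtension, "\n")
})

#' @describeIn ScoringScheme substitution matrix accessor
#' @param x,object a \code{ScoringScheme}
#' @export
substitutionMatrix <- function(x) x@matrix

#' @describeIn ScoringScheme gap opening penalty accessor
#' @export
gapOpening <- function(x) x@gapOpening

#' @describeIn ScoringScheme gap extension penalty accessor
#' @export
gapExtension <- function(x) x@gapExtension

#' Parse a substitution matrix in NCBI/EMBOSS text format
#'
#' Reads the standard whitespace-delimited matrix layout: \code{#} comment
#' lines, a header row of single-character symbols, then one labelled row
#' per symbol.  The parsed matrix must be symmetric.
#'
#' @param file path to a matrix file, or a character vector of lines
#'   (anything of length > 1, or containing a newline, is treated as
#'   file contents rather than a path).
#' @return symmetric numeric matrix with symbol dimnames.
#' @examples
#' b62 <- loadSubstitutionMatrix(
#'   system.file("extdata", "BLOSUM62.txt", package = "PartialAlign"))
#' b62["A", "A"]  # 4
#' @export
loadSubstitutionMatrix <- function(file) {
  lines <- if (length(file) > 1L || grepl("\n", file[1L], fixed = TRUE)) {
    unlist(strsplit(file, "\n", fixed = TRUE))
  } else {
    if (!file.exists(file)) stop("matrix file not found: ", file)
    readLines(file)
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  if (length(body) < 2L) stop("matrix text has no header/data rows")

  header <- strsplit(trimws(body[1L]), "\\s+")[[1L]]
  if (any(nchar(header) != 1L))
    stop("malformed header at line ", lineno[1L],
         ": symbols must be single characters")
  n <- length(header)
  if (length(body) - 1L != n)
    stop("expected ", n, " data rows, found ", length(body) - 1L)

  mat <- matrix(NA_real_, n, n, dimnames = list(header, header))
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(body[k + 1L]), "\\s+")[[1L]]
    if (length(fields) != n + 1L)
      stop("ragged row at line ", lineno[k + 1L], ": expected ",
           n + 1L, " fields, found ", length(fields))
    lab <- fields[1L]
    if (!lab %in% header)
      stop("unknown row label '", lab, "' at line ", lineno[k + 1L])
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals))
      stop("non-numeric score at line ", lineno[k + 1L])
    mat[lab, ] <- vals
  }
  asym <- which(mat != t(mat), arr.ind = TRUE)
  if (nrow(asym)) {
    i <- asym[1L, 1L]; j <- asym[1L, 2L]
    stop("asymmetric matrix: score(", header[i], ",", header[j], ") = ",
         mat[i, j], " but score(", header[j], ",", header[i], ") = ",
         mat[j, i], " (row at line ", lineno[i + 1L], ")")
  }
  mat
}

#' Simple nucleotide substitution matrix
#'
#' @param match,mismatch scores for identical / differing bases.
#' @return 4x4 symmetric matrix over A, C, G, T.
#' @export
nucleotideMatrix <- function(match = 5, mismatch = -4) {
  al <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(al, al))
  diag(m) <- match
  m
}

#' Bundled BLOSUM62 scoring scheme
#'
#' BLOSUM62 with the package's default affine penalties (opening 10,
#' extension 0.5).  Although BLOSUM62 is an amino-acid matrix, its alphabet
#' contains A/C/G/T and it is commonly fed to generic local aligners for DNA.
#'
#' @inheritParams ScoringScheme
#' @return A [ScoringScheme-class].
#' @export
blosum62Scheme <- function(gapOpening = 10, gapExtension = 0.5) {
  ScoringScheme(
    loadSubstitutionMatrix(
      system.file("extdata", "BLOSUM62.txt", package = "PartialAlign")),
    gapOpening, gapExtension)
}

#' Match/mismatch nucleotide scoring scheme
#' @param match,mismatch scores for identical / differing bases.
#' @inheritParams ScoringScheme
#' @return A [ScoringScheme-class].
#' @export
nucleotideScheme <- function(match = 5, mismatch = -4,
                             gapOpening = 10, gapExtension = 0.5) {
  ScoringScheme(nucleotideMatrix(match, mismatch), gapOpening, gapExtension)
}

#' Look up a scoring scheme by name (used by the command-line interface)
#' @param name \code{"blosum62"}, \code{"nucleotide"}, or a path to a matrix
#'   file in NCBI/EMBOSS format.
#' @inheritParams ScoringScheme
#' @return A [ScoringScheme-class].
#' @export
schemeByName <- function(name, gapOpening = 10, gapExtension = 0.5) {
  lname <- tolower(name)
  if (lname %in% c("blosum62", "blosum"))
    return(blosum62Scheme(gapOpening, gapExtension))
  if (lname %in% c("nucleotide", "nuc", "dna"))
    return(nucleotideScheme(gapOpening = gapOpening,
                            gapExtension = gapExtension))
  ScoringScheme(loadSubstitutionMatrix(name), gapOpening, gapExtension)
}
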