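#' Optimal local alignment of a query against a reference
#'
#' Result container for one Smith-Waterman alignment.  All coordinates are
#' 1-based inclusive.  An empty alignment (nothing scores above zero) has
#' score 0, zero matches and \code{NA} coordinates.
#'
#' @slot queryStart,queryEnd 1-based inclusive interval of the query
#'   consumed by the alignment.
#' @slot refStart,refEnd 1-based inclusive interval of the reference.
#' @slot alignedQuery,alignedRef equal-length aligned strings over the
#'   sequence alphabet plus \code{"-"}; no column has a gap in both.
#' @slot score optimal local alignment score (never negative).
#' @slot matches number of identical aligned residue pairs.
#' @slot queryLength full length of the query sequence as given; the
#'   denominator of the similarity ratio.
#'
#' @seealso [smithWaterman()], [similarityRatio()]
#' @export
setClass("LocalAlignment",
  representation(queryStart = "integer", queryEnd = "integer",
                 refStart = "integer", refEnd = "integer",
                 alignedQuery = "character", alignedRef = "character",
                 score = "numeric", matches = "integer",
                 queryLength = "integer"))

setValidity("LocalAlignment", function(object) {
  msg <- character()
  if (object@score < 0) msg <- c(msg, "score must be non-negative")
  if (nchar(object@alignedQuery) != nchar(object@alignedRef))
    msg <- c(msg, "aligned strings must have equal length")
  if (!is.na(object@queryStart)) {
    if (object@queryStart > object@queryEnd ||
        object@refStart > object@refEnd)
      msg <- c(msg, "interval starts must not exceed ends")
    dq <- gsub("-", "", object@alignedQuery, fixed = TRUE)
    if (nchar(dq) != object@queryEnd - object@queryStart + 1L)
      msg <- c(msg, "alignedQuery must spell the consumed query interval")
    dr <- gsub("-", "", object@alignedRef, fixed = TRUE)
    if (nchar(dr) != object@refEnd - object@refStart + 1L)
      msg <- c(msg, "alignedRef must spell the consumed reference interval")
    qg <- strsplit(object@alignedQuery, "")[[1L]] == "-"
    rg <- strsplit(object@alignedRef, "")[[1L]] == "-"
    if (any(qg & rg)) msg <- c(msg, "column with a gap in both sequences")
  }
  if (object@matches > object@queryLength)
    msg <- c(msg, "matches cannot exceed the query length")
  if (length(msg)) msg else TRUE
})

#' @describeIn LocalAlignment consumed query interval as an IRanges
#' @param x a \code{LocalAlignment}
#' @export
queryRange <- function(x) IRanges::IRanges(x@queryStart, x@queryEnd)

#' @describeIn LocalAlignment consumed reference interval as an IRanges
#' @export
refRange <- function(x) IRanges::IRanges(x@refStart, x@refEnd)

#' @describeIn LocalAlignment number of identical aligned pairs
#' @export
matchCount <- function(x) x@matches

#' @describeIn LocalAlignment alignment score
#' @export
alignmentScore <- function(x) x@score

#' @describeIn LocalAlignment number of query bases consumed
#'   (\code{queryEnd - queryStart + 1}; 0 for an empty alignment)
#' @export
consumedBases <- function(x)
  if (is.na(x@queryStart)) 0L else x@queryEnd - x@queryStart + 1L

setMethod("show", "LocalAlignment", function(object) {
  cat("LocalAlignment: score ", format(object@score),
      ", matches ", object@matches, "/", object@queryLength,
      " (similarity ratio ",
      format(round(similarityRatio(object), 4)), ")\n", sep = "")
  if (is.na(object@queryStart)) {
    cat("  <empty alignment>\n")
    return(invisible(NULL))
  }
  cat("  query [", object@queryStart, ", ", object@queryEnd,
      "]  reference [", object@refStart, ", ", object@refEnd, "]\n", sep = "")
  aq <- object@alignedQuery
  ar <- object@alignedRef
  qs <- strsplit(aq, "")[[1L]]
  rs <- strsplit(ar, "")[[1L]]
  mid <- ifelse(qs == rs & qs != "-", "|", " ")
  for (off in seq(1L, nchar(aq), by = 60L)) {
    idx <- off:min(off + 59L, nchar(aq))
    cat("  Q ", substr(aq, idx[1L], idx[length(idx)]), "\n",
        "    ", paste(mid[idx], collapse = ""), "\n",
        "  R ", substr(ar, idx[1L], idx[length(idx)]), "\n", sep = "")
  }
  invisible(NULL)
})

# ---- internal sequence / scheme plumbing -----------------------------------

#' @noRd
.asSeqChar <- function(x, what = "sequence") {
  if (methods::is(x, "XStringSet")) {
    if (length(x) != 1L) stop(what, " must be a single sequence")
    x <- as.character(x)
  } else if (methods::is(x, "XString")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string or Biostrings object")
  x <- toupper(x)
  if (nchar(x) == 0L) stop(what, " must be non-empty")
  x
}

# Alphabet lookup used by the C++ core.  The residue N is always scored 0
# against everything (neutral placeholder base), overriding any N row the
# matrix may define for its own alphabet.
#' @noRd
.schemeLookup <- function(scheme) {
  m <- scheme@matrix
  al <- rownames(m)
  if (!"N" %in% al) {
    m <- rbind(cbind(m, N = 0), N = 0)
    al <- rownames(m)
  } else {
    m["N", ] <- 0
    m[, "N"] <- 0
  }
  codemap <- integer(256)
  codemap[as.integer(charToRaw(paste(al, collapse = ""))) + 1L] <-
    seq_along(al)
  list(lookup = m, codemap = codemap, alphabet = al)
}

#' @noRd
.encodeSeq <- function(s, lk, what = "sequence") {
  codes <- lk$codemap[as.integer(charToRaw(s)) + 1L]
  if (any(codes == 0L)) {
    p <- which(codes == 0L)[1L]
    stop("unscoreable residue '", substr(s, p, p), "' at position ", p,
         " of ", what)
  }
  codes - 1L
}

# Score / match-count / interval of the optimal local alignment for every
# query prefix; row L corresponds to query[1..L].
#' @noRd
.prefixScan <- function(qcodes, rcodes, lk, scheme) {
  cpp_sw_prefix_scan(qcodes, rcodes, lk$lookup,
                     scheme@gapOpening, scheme@gapExtension)
}

#' @noRd
.swStatsFromCodes <- function(qcodes, rcodes, lk, scheme) {
  scan <- .prefixScan(qcodes, rcodes, lk, scheme)
  row <- scan[length(qcodes), ]
  list(score = row[1L], matches = as.integer(row[2L]),
       qs = as.integer(row[3L]), qe = as.integer(row[4L]),
       rs = as.integer(row[5L]), re = as.integer(row[6L]))
}

#' @noRd
.swAlignFromCodes <- function(qcodes, rcodes, lk, scheme, qstr, rstr) {
  res <- cpp_sw_traceback(qcodes, rcodes, lk$lookup,
                          scheme@gapOpening, scheme@gapExtension, qstr, rstr)
  new("LocalAlignment",
      queryStart = res$qs, queryEnd = res$qe,
      refStart = res$rs, refEnd = res$re,
      alignedQuery = res$alignedQuery, alignedRef = res$alignedRef,
      score = res$score, matches = res$matches,
      queryLength = nchar(qstr))
}

# ---- exported operations ----------------------------------------------------

#' Smith-Waterman local alignment with affine gap penalties
#'
#' Computes the optimal local alignment of \code{query} against
#' \code{reference} under the scheme's substitution matrix and affine gap
#' penalties (a gap of length L costs \code{gapOpening + (L-1) *
#' gapExtension}).  The traceback is deterministic: on equal cell scores the
#' diagonal move is preferred over a gap in the reference over a gap in the
#' query, and among equally scoring end cells the one with the smallest
#' (reference end, query end) pair is reported.
#'
#' @param query,reference character strings or Biostrings objects; residues
#'   must be present in the scheme's alphabet (or be \code{N}, which scores
#'   0 against everything).
#' @param scheme a [ScoringScheme-class]; defaults to BLOSUM62 with gap
#'   opening 10 and extension 0.5.
#' @return A [LocalAlignment-class].
#' @examples
#' aln <- smithWaterman("ACGT", "TTACGTTT")
#' alignmentScore(aln)  # 4 + 9 + 6 + 5 = 24
#' @export
smithWaterman <- function(query, reference, scheme = blosum62Scheme()) {
  q <- .asSeqChar(query, "query")
  r <- .asSeqChar(reference, "reference")
  lk <- .schemeLookup(scheme)
  qc <- .encodeSeq(q, lk, "query")
  rc <- .encodeSeq(r, lk, "reference")
  .swAlignFromCodes(qc, rc, lk, scheme, q, r)
}

#' Similarity ratio of an alignment
#'
#' The fraction of bases of the full query sequence that were matched
#' identically in the optimal local alignment: \code{matches / queryLength}.
#' The denominator is the entire query length as supplied, not the aligned
#' span, so unaligned query bases count against the ratio.
#'
#' @param alignment a [LocalAlignment-class].
#' @param queryLength full length of the query; defaults to the length
#'   recorded in the alignment.
#' @return a number in [0, 1].
#' @export
similarityRatio <- function(alignment, queryLength = alignment@queryLength) {
  queryLength <- as.integer(queryLength)
  if (is.na(queryLength) || queryLength < 1L)
    stop("queryLength must be a positive integer")
  if (queryLength < alignment@matches)
    stop("inconsistent inputs: queryLength (", queryLength,
         ") is smaller than the match count (", alignment@matches, ")")
  alignment@matches / queryLength
}

#' Deletion-position estimate of classical Smith-Waterman
#'
#' The baseline method: one local alignment of the whole query, whose number
#' of consumed query bases (\code{queryEnd - queryStart + 1}) is taken as
#' the estimated former-part length.  When the query spans a large deletion
#' the alignment typically covers the longer side plus spurious gapped
#' matches, so this estimate carries a large error.
#'
#' @inheritParams smithWaterman
#' @return integer estimate of the deletion position in query coordinates.
#' @export
classicalSWBoundary <- function(query, reference, scheme = blosum62Scheme()) {
  q <- .asSeqChar(query, "query")
  r <- .asSeqChar(reference, "reference")
  lk <- .schemeLookup(scheme)
  qc <- .encodeSeq(q, lk, "query")
  rc <- .encodeSeq(r, lk, "reference")
  st <- .swStatsFromCodes(qc, rc, lk, scheme)
  if (st$score <= 0) 0L else st$qe - st$qs + 1L
}
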