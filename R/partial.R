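#' Result of a partial (split) alignment
#'
#' Produced by [incrementalPartialAlign()] and [binaryPartialAlign()].
#' Coordinates are 1-based inclusive.  Writing \eqn{[a, b]} for the
#' reference interval matched by the former part and \eqn{[c, d]} for the
#' latter part, the deleted reference interval is \eqn{[b + 1, c - 1]} with
#' length \eqn{c - b - 1}.
#'
#' @slot method \code{"incremental"} or \code{"binary"}.
#' @slot former,latter [LocalAlignment-class] of the two query parts, or
#'   \code{NULL} when no split was made.
#' @slot boundary estimated former-part length in query coordinates
#'   (\code{NA} when no deletion was called).
#' @slot deletionStart,deletionEnd,deletionLength deleted reference
#'   interval \eqn{[b+1, c-1]} and its length (\code{NA} unless
#'   status is \code{"deletion"}).
#' @slot trace data frame of split states visited (iteration,
#'   former/latter lengths, step size, part similarity ratios).
#' @slot swCalls number of Smith-Waterman invocations performed.
#' @slot status one of \code{"no_deletion"} (whole query aligns acceptably),
#'   \code{"deletion"}, \code{"adjacent"} (parts map side by side, nothing
#'   deleted between them) or \code{"discordant"} (latter part maps at or
#'   before the former part).
#' @slot converged \code{FALSE} when a search terminated without meeting its
#'   stopping rule and reported the best split seen (the one maximising the
#'   smaller of the two part ratios).
#' @slot fullRatio,fullConsumed similarity ratio and consumed-base count of
#'   the initial whole-query alignment; \code{fullConsumed} is the fallback
#'   deletion-position estimate when no split boundary exists.
#' @slot queryLength,threshold,minLength the inputs the search ran with.
#' @export
setClass("PartialAlignmentResult",
  representation(method = "character", former = "ANY", latter = "ANY",
                 boundary = "integer", deletionStart = "integer",
                 deletionEnd = "integer", deletionLength = "integer",
                 trace = "data.frame", swCalls = "integer",
                 status = "character", converged = "logical",
                 fullRatio = "numeric", fullConsumed = "integer",
                 queryLength = "integer", threshold = "numeric",
                 minLength = "integer"))

setValidity("PartialAlignmentResult", function(object) {
  msg <- character()
  if (!object@status %in% c("no_deletion", "deletion", "adjacent",
                            "discordant"))
    msg <- c(msg, "unknown status")
  if (object@status == "no_deletion" &&
      (!is.na(object@boundary) || !is.null(object@former)))
    msg <- c(msg, "no_deletion results must not carry a split")
  if (object@status == "deletion") {
    if (is.na(object@deletionLength) ||
        object@deletionLength !=
          object@deletionEnd - object@deletionStart + 1L)
      msg <- c(msg, "deletionLength must equal deletionEnd - deletionStart + 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PartialAlignmentResult estimated former-part length
#' @param x a \code{PartialAlignmentResult}
#' @export
boundaryEstimate <- function(x) x@boundary

#' @describeIn PartialAlignmentResult deleted reference interval as IRanges
#'   (zero-length when no deletion was called)
#' @export
deletionRange <- function(x) {
  if (is.na(x@deletionStart)) IRanges::IRanges()
  else IRanges::IRanges(x@deletionStart, x@deletionEnd)
}

#' @describeIn PartialAlignmentResult number of Smith-Waterman invocations
#' @export
swCalls <- function(x) x@swCalls

#' @describeIn PartialAlignmentResult data frame of visited split states
#' @export
alignmentTrace <- function(x) x@trace

#' @describeIn PartialAlignmentResult deletion-position estimate used for
#'   error measurement: the split boundary when one was found, otherwise the
#'   consumed-base count of the whole-query alignment (the classical
#'   Smith-Waterman estimate).
#' @export
estimatedBoundary <- function(x)
  if (is.na(x@boundary)) x@fullConsumed else x@boundary

setMethod("show", "PartialAlignmentResult", function(object) {
  cat("PartialAlignmentResult (", object@method, "): status ",
      object@status, if (!object@converged) " [not converged]", "\n",
      sep = "")
  cat("  query length ", object@queryLength, ", threshold ",
      object@threshold, ", min length ", object@minLength,
      ", SW calls ", object@swCalls, "\n", sep = "")
  if (!is.na(object@boundary)) {
    cat("  boundary estimate:", object@boundary, "\n")
    if (!is.null(object@former) && !is.na(object@former@refStart))
      cat("  former part -> reference [", object@former@refStart, ", ",
          object@former@refEnd, "]\n", sep = "")
    if (!is.null(object@latter) && !is.na(object@latter@refStart))
      cat("  latter part -> reference [", object@latter@refStart, ", ",
          object@latter@refEnd, "]\n", sep = "")
  }
  if (object@status == "deletion")
    cat("  deletion: reference [", object@deletionStart, ", ",
        object@deletionEnd, "], length ", object@deletionLength,
        "\n", sep = "")
  invisible(NULL)
})

# ---- elementary operations --------------------------------------------------

#' Deletion interval between two part mappings
#'
#' Given the reference position \code{b} where the former part's mapping
#' ends and the position \code{c} where the latter part's mapping starts,
#' the deleted interval is \eqn{[b + 1, c - 1]} with length
#' \eqn{c - b - 1}.
#'
#' @param formerRefEnd reference end of the former part's mapping (b).
#' @param latterRefStart reference start of the latter part's mapping (c).
#' @return list with \code{start}, \code{end} (the deleted interval) and
#'   \code{length}.
#' @examples
#' callDeletion(1427, 2071)$length  # 643
#' @export
callDeletion <- function(formerRefEnd, latterRefStart) {
  b <- as.integer(formerRefEnd)
  c <- as.integer(latterRefStart)
  if (is.na(b) || is.na(c) || b < 1L || c < 1L)
    stop("positions must be positive integers")
  if (c <= b + 1L)
    stop("no deletion between parts: latter mapping starts at ", c,
         " which is not beyond former mapping end ", b, " + 1")
  list(start = b + 1L, end = c - 1L, length = c - b - 1L)
}

#' Estimated deletion position error (EDPE)
#'
#' Absolute difference, in bases, between the estimated and the true
#' deletion boundary position within the query.
#'
#' @param estimated,true boundary positions (former-part lengths) in query
#'   coordinates.
#' @return non-negative integer error in bp.
#' @examples
#' edpe(37, 27)  # 10
#' @export
edpe <- function(estimated, true) {
  if (any(is.na(estimated)) || any(is.na(true)))
    stop("boundaries must not be NA")
  abs(as.integer(estimated) - as.integer(true))
}

#' Step size of the binary split search
#'
#' At iteration \eqn{i} the boundary moves by
#' \eqn{k = \lfloor l_{query} / 2^{i+1} \rfloor} bases.  A return value of
#' 0 signals the caller that the step schedule is exhausted.
#'
#' @param queryLength total query length.
#' @param iteration iteration number, starting at 1.
#' @return non-negative integer step.
#' @examples
#' stepSize(40, 1)  # 10
#' stepSize(40, 2)  # 5
#' stepSize(40, 3)  # 2
#' @export
stepSize <- function(queryLength, iteration) {
  queryLength <- as.integer(queryLength)
  iteration <- as.integer(iteration)
  if (is.na(queryLength) || queryLength < 1L)
    stop("queryLength must be a positive integer")
  if (is.na(iteration) || iteration < 1L)
    stop("iteration must be >= 1")
  as.integer(queryLength %/% 2^(iteration + 1))
}

# ---- shared machinery -------------------------------------------------------

#' @noRd
.checkPartialArgs <- function(l, threshold, minLength) {
  if (minLength < 1L) stop("minLength must be >= 1")
  if (2L * minLength > l)
    stop("query of length ", l, " is shorter than 2 * minLength (",
         2L * minLength, ")")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
}

#' @noRd
.emptyTrace <- function() {
  data.frame(iteration = integer(), former_length = integer(),
             latter_length = integer(), step = integer(),
             former_ratio = numeric(), latter_ratio = numeric())
}

#' @noRd
.newPartialResult <- function(method, l, threshold, minLength, status,
                              trace, swCalls, fullRatio, fullConsumed,
                              boundary = NA_integer_, former = NULL,
                              latter = NULL, del = NULL, converged = TRUE) {
  new("PartialAlignmentResult", method = method,
      former = former, latter = latter,
      boundary = as.integer(boundary),
      deletionStart = if (is.null(del)) NA_integer_ else del$start,
      deletionEnd = if (is.null(del)) NA_integer_ else del$end,
      deletionLength = if (is.null(del)) NA_integer_ else del$length,
      trace = trace, swCalls = as.integer(swCalls), status = status,
      converged = converged, fullRatio = fullRatio,
      fullConsumed = as.integer(fullConsumed),
      queryLength = as.integer(l), threshold = as.numeric(threshold),
      minLength = as.integer(minLength))
}

# Align both parts (traceback), call the deletion, classify the status.
#' @noRd
.finishSplit <- function(method, q, qc, rc, lk, scheme, l, threshold,
                         minLength, boundary, trace, swCalls, fullRatio,
                         fullConsumed, converged = TRUE) {
  former <- latter <- NULL
  if (boundary >= 1L)
    former <- .swAlignFromCodes(qc[seq_len(boundary)], rc, lk, scheme,
                                substr(q, 1L, boundary), attr(rc, "str"))
  if (boundary < l)
    latter <- .swAlignFromCodes(qc[(boundary + 1L):l], rc, lk, scheme,
                                substr(q, boundary + 1L, l), attr(rc, "str"))
  status <- "deletion"
  del <- NULL
  if (is.null(former) || is.null(latter) ||
      is.na(former@refEnd) || is.na(latter@refStart)) {
    status <- "discordant"
  } else {
    b <- former@refEnd
    cc <- latter@refStart
    if (cc <= b) status <- "discordant"
    else if (cc == b + 1L) status <- "adjacent"
    else del <- callDeletion(b, cc)
  }
  .newPartialResult(method, l, threshold, minLength, status, trace,
                    swCalls, fullRatio, fullConsumed, boundary = boundary,
                    former = former, latter = latter, del = del,
                    converged = converged)
}

# ---- the two split searches -------------------------------------------------

#' Incremental split search for a large deletion
#'
#' Aligns the whole query first; a similarity ratio at or above
#' \code{threshold} means small gaps explain the query and no deletion is
#' called.  Otherwise former-part lengths \code{minLength, minLength + 1,
#' ...} are tried in turn, each prefix aligned against the full reference,
#' until the prefix similarity ratio first drops below \code{threshold} at
#' some length L*; the boundary estimate is L* - 1 (the last length whose
#' ratio still met the threshold), the remaining (latter) part is aligned
#' separately, and the deleted reference interval between the two mappings
#' is reported.  Former-part lengths run up to the full query length minus
#' one, so the final latter part may be shorter than \code{minLength}.
#'
#' The implementation evaluates all prefixes in a single dynamic-programming
#' pass (each prefix's optimum is read off row by row), which is
#' bit-identical to aligning every prefix separately; \code{swCalls} counts
#' the alignments the algorithm specifies, not the fused pass.
#'
#' @inheritParams smithWaterman
#' @param threshold similarity-ratio threshold in (0, 1]; a part is
#'   acceptably explained when its ratio is at least this value.
#' @param minLength minimum part length at which the scan starts (and the
#'   shortest latter part considered).
#' @return A [PartialAlignmentResult-class].
#' @seealso [binaryPartialAlign()] for the logarithmic-time search.
#' @export
incrementalPartialAlign <- function(query, reference, threshold = 0.9,
                                    minLength = 20L,
                                    scheme = blosum62Scheme()) {
  q <- .asSeqChar(query, "query")
  r <- .asSeqChar(reference, "reference")
  l <- nchar(q)
  minLength <- as.integer(minLength)
  .checkPartialArgs(l, threshold, minLength)

  lk <- .schemeLookup(scheme)
  qc <- .encodeSeq(q, lk, "query")
  rc <- .encodeSeq(r, lk, "reference")
  attr(rc, "str") <- r

  scan <- .prefixScan(qc, rc, lk, scheme)
  fullMatches <- scan[l, 2L]
  fullRatio <- fullMatches / l
  fullConsumed <- if (scan[l, 1L] > 0) scan[l, 4L] - scan[l, 3L] + 1L else 0L

  if (fullRatio >= threshold)
    return(.newPartialResult("incremental", l, threshold, minLength,
                             "no_deletion", .emptyTrace(), 1L,
                             fullRatio, fullConsumed))

  Ls <- minLength:(l - 1L)  # latter part may end up shorter than minLength
  ratios <- scan[Ls, 2L] / Ls
  below <- which(ratios < threshold)
  trace <- data.frame(iteration = seq_along(Ls),
                      former_length = Ls, latter_length = l - Ls,
                      step = 1L, former_ratio = ratios,
                      latter_ratio = NA_real_)
  if (!length(below)) {
    # every former-part length met the threshold: the query aligns
    # acceptably piecewise, no single boundary can be called
    return(.newPartialResult("incremental", l, threshold, minLength,
                             "no_deletion", trace,
                             1L + length(Ls), fullRatio, fullConsumed))
  }
  Lstar <- Ls[below[1L]]
  trace <- trace[seq_len(below[1L]), ]
  boundary <- Lstar - 1L
  swCalls <- 1L + below[1L] + 1L  # full query + prefixes tried + latter part
  .finishSplit("incremental", q, qc, rc, lk, scheme, l, threshold,
               minLength, boundary, trace, swCalls, fullRatio, fullConsumed)
}

#' Binary-search-style split search for a large deletion
#'
#' Aligns the whole query first; a similarity ratio at or above
#' \code{threshold} means no deletion.  Otherwise the query is divided into
#' two equal parts and both parts are aligned separately each iteration.
#' If both part ratios are strictly above \code{threshold} the split is
#' accepted as the deletion boundary.  If not, the part with the larger
#' ratio is lengthened (the other shortened) by the step
#' \eqn{k = \lfloor l_{query} / 2^{i+1} \rfloor}, which halves every
#' iteration, so the search needs O(log2 l) alignments.  When the step
#' schedule is exhausted (k = 0) or a step would leave the feasible range,
#' the best split seen (maximising the smaller part ratio) is reported with
#' \code{converged = FALSE}.
#'
#' The stopping rule compares strictly ("above the threshold"): a part
#' ratio exactly equal to \code{threshold} does not stop the search.
#' \code{minLength} bounds the initial split; intermediate iterations may
#' evaluate shorter parts while homing in on the boundary.
#'
#' @inheritParams incrementalPartialAlign
#' @return A [PartialAlignmentResult-class].
#' @examples
#' ref <- syntheticReference(500, seed = 1)
#' qry <- paste0(substr(ref, 21, 60), substr(ref, 301, 330))
#' res <- binaryPartialAlign(qry, ref)
#' @export
binaryPartialAlign <- function(query, reference, threshold = 0.9,
                               minLength = 20L,
                               scheme = blosum62Scheme()) {
  q <- .asSeqChar(query, "query")
  r <- .asSeqChar(reference, "reference")
  l <- nchar(q)
  minLength <- as.integer(minLength)
  .checkPartialArgs(l, threshold, minLength)

  lk <- .schemeLookup(scheme)
  qc <- .encodeSeq(q, lk, "query")
  rc <- .encodeSeq(r, lk, "reference")
  attr(rc, "str") <- r

  full <- .swStatsFromCodes(qc, rc, lk, scheme)
  fullRatio <- full$matches / l
  fullConsumed <- if (full$score > 0) full$qe - full$qs + 1L else 0L
  swCalls <- 1L
  if (fullRatio >= threshold)
    return(.newPartialResult("binary", l, threshold, minLength,
                             "no_deletion", .emptyTrace(), swCalls,
                             fullRatio, fullConsumed))

  fl <- l %/% 2L
  fl <- max(minLength, min(fl, l - minLength))
  i <- 1L
  trace <- .emptyTrace()
  bestFl <- NA_integer_
  bestMin <- -Inf
  boundary <- NA_integer_
  converged <- FALSE

  repeat {
    rf <- .swStatsFromCodes(qc[seq_len(fl)], rc, lk, scheme)$matches / fl
    rl <- .swStatsFromCodes(qc[(fl + 1L):l], rc, lk, scheme)$matches /
      (l - fl)
    swCalls <- swCalls + 2L
    k <- stepSize(l, i)
    trace <- rbind(trace, data.frame(
      iteration = i, former_length = fl, latter_length = l - fl,
      step = k, former_ratio = rf, latter_ratio = rl))
    if (min(rf, rl) > bestMin) { bestMin <- min(rf, rl); bestFl <- fl }

    if (rf > threshold && rl > threshold) {
      boundary <- fl
      converged <- TRUE
      break
    }
    if (k == 0L) break
    newFl <- if (rf >= rl) fl + k else fl - k  # tie lengthens the former part
    if (newFl < 1L || newFl > l - 1L) break    # would leave feasible range
    fl <- newFl
    i <- i + 1L
  }
  if (is.na(boundary)) boundary <- bestFl
  .finishSplit("binary", q, qc, rc, lk, scheme, l, threshold, minLength,
               boundary, trace, swCalls, fullRatio, fullConsumed,
               converged = converged)
}
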