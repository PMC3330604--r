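# Simulation harness: two-fragment deletion queries drawn from a reference,
# and per-length-bin EDPE summaries for the three boundary estimators.

#' Evaluate code with a temporary RNG seed
#' @noRd
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Random reference sequence
#'
#' Uniform i.i.d. bases over A, C, G, T from a seeded generator; the same
#' seed and length always give the same sequence.
#'
#' @param length reference length (>= 1).
#' @param seed integer seed, or \code{NULL} to draw from the current RNG
#'   state.
#' @return a single character string.
#' @examples
#' syntheticReference(8, seed = 1)
#' @export
syntheticReference <- function(length, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("length must be a positive integer")
  .withSeed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

#' Simulated two-fragment deletion query
#'
#' Emulates a query read spanning one large deletion: two subsequences of
#' the reference are concatenated.  The total query length is drawn
#' uniformly from \code{lengthRange}, split uniformly into two fragment
#' lengths of at least \code{minFragment} each; the former fragment is
#' placed uniformly and the latter uniformly among downstream positions
#' leaving a gap of at least \code{minDeletion} bases (the former fragment
#' always lies upstream, so the truth record always describes a real,
#' positively oriented deletion).  Optionally each query base is substituted
#' with probability \code{mutationRate} to emulate sequencing errors or
#' variants.
#'
#' Uses the current RNG state; seed it with \code{set.seed()} or the
#' \code{seed} argument for reproducibility.
#'
#' @param reference reference sequence (character string).
#' @param lengthRange integer two-vector, inclusive range of total query
#'   lengths.
#' @param minFragment minimum fragment length (both fragments).
#' @param minDeletion minimum deleted-interval length separating the two
#'   fragments; the default keeps deletions large relative to the affine
#'   gap cost so a single bridged alignment is not favoured.
#' @param mutationRate per-base substitution probability applied to the
#'   finished query (default 0: exact fragments).
#' @param seed optional integer seed.
#' @return list with \code{query} (character) and \code{truth}, a one-row
#'   data frame with former/latter fragment coordinates, the true boundary
#'   (former fragment length) and the true deletion length.
#' @export
makeQuery <- function(reference, lengthRange = c(100L, 999L),
                      minFragment = 20L, minDeletion = 1000L,
                      mutationRate = 0, seed = NULL) {
  .withSeed(seed, {
    r <- .asSeqChar(reference, "reference")
    R <- nchar(r)
    lengthRange <- as.integer(lengthRange)
    minFragment <- as.integer(minFragment)
    minDeletion <- as.integer(minDeletion)
    if (length(lengthRange) != 2L || any(is.na(lengthRange)) ||
        lengthRange[1L] > lengthRange[2L] || lengthRange[1L] < 2L)
      stop("lengthRange must be an increasing pair of integers >= 2")
    if (minFragment < 1L) stop("minFragment must be >= 1")
    if (2L * minFragment > lengthRange[1L])
      stop("lengthRange[1] (", lengthRange[1L],
           ") cannot host two fragments of minFragment ", minFragment)
    if (R < lengthRange[2L] + minDeletion)
      stop("reference of length ", R, " is too short for queries up to ",
           lengthRange[2L], " plus a deletion of at least ", minDeletion)

    L <- sample(lengthRange[1L]:lengthRange[2L], 1L)
    lf <- sample(minFragment:(L - minFragment), 1L)
    ll <- L - lf
    s1max <- R - (lf + minDeletion + ll) + 1L
    s1 <- sample(s1max, 1L)
    s2 <- sample((s1 + lf + minDeletion):(R - ll + 1L), 1L)

    query <- paste0(substr(r, s1, s1 + lf - 1L),
                    substr(r, s2, s2 + ll - 1L))
    if (mutationRate > 0) query <- .mutate(query, mutationRate)
    truth <- data.frame(
      former_ref_start = s1, former_ref_end = s1 + lf - 1L,
      latter_ref_start = s2, latter_ref_end = s2 + ll - 1L,
      true_boundary = lf,
      true_deletion_length = s2 - (s1 + lf - 1L) - 1L)
    list(query = query, truth = truth)
  })
}

#' @noRd
.mutate <- function(s, rate) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) {
    ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Demonstration fixture with an unambiguous breakpoint
#'
#' Builds a seeded random reference and a two-fragment deletion query whose
#' breakpoint is unambiguous for the split searches at the given
#' similarity-ratio threshold(s): each fragment occurs exactly once in the
#' reference, and every threshold decision the searches take on it equals
#' the decision taken on the idealized two-fragment model in which each
#' part matches exactly its own fragment bases — so the searches follow
#' the model trace deterministically.  Chance matches around the junction
#' that would flip a decision cause the placement to be resampled.  (On
#' real genomes a deletion whose flanks resemble the deleted interval has
#' an intrinsically ambiguous position; a demonstration of exact boundary
#' recovery needs that ambiguity absent.)
#'
#' @param refLength reference length.
#' @param formerLength,latterLength fragment lengths.
#' @param minDeletion minimum separation between the fragments.
#' @param seed integer seed.
#' @param threshold similarity-ratio threshold(s) the fixture must be
#'   unambiguous at (a vector is checked against every value).
#' @param minLength minimum part length the searches will be run with.
#' @param scheme scoring scheme used for the consistency check.
#' @param maxTries resampling budget before giving up.
#' @param formerStart,latterStart optional fixed reference start positions
#'   for the two fragments; when given, only the reference is resampled
#'   until the fixture is unambiguous at these exact coordinates.
#' @return list with \code{reference}, \code{query} and \code{truth} (as in
#'   [makeQuery()]).
#' @export
unambiguousDeletionFixture <- function(refLength = 500L, formerLength = 27L,
                                       latterLength = 13L,
                                       minDeletion = 100L, seed = NULL,
                                       threshold = 0.9, minLength = 20L,
                                       scheme = blosum62Scheme(),
                                       maxTries = 2000L,
                                       formerStart = NULL,
                                       latterStart = NULL) {
  .withSeed(seed, {
    lf <- as.integer(formerLength)
    ll <- as.integer(latterLength)
    l <- lf + ll
    lk <- .schemeLookup(scheme)
    for (try in seq_len(maxTries)) {
      r <- syntheticReference(refLength)
      R <- nchar(r)
      s1max <- R - (lf + minDeletion + ll) + 1L
      if (s1max < 1L)
        stop("reference too short for the requested fragments and deletion")
      if (!is.null(formerStart)) {
        s1 <- as.integer(formerStart)
        s2 <- as.integer(latterStart)
        if (s2 - (s1 + lf - 1L) - 1L < minDeletion)
          stop("fixed coordinates leave less than minDeletion between parts")
      } else {
        s1 <- sample(s1max, 1L)
        s2 <- sample((s1 + lf + minDeletion):(R - ll + 1L), 1L)
      }
      frag1 <- substr(r, s1, s1 + lf - 1L)
      frag2 <- substr(r, s2, s2 + ll - 1L)
      if (.countOccurrences(r, frag1) != 1L ||
          .countOccurrences(r, frag2) != 1L) next
      query <- paste0(frag1, frag2)
      if (!.splitSearchConsistent(query, r, lf, threshold,
                                  as.integer(minLength), lk, scheme)) next
      truth <- data.frame(
        former_ref_start = s1, former_ref_end = s1 + lf - 1L,
        latter_ref_start = s2, latter_ref_end = s2 + ll - 1L,
        true_boundary = lf,
        true_deletion_length = s2 - (s1 + lf - 1L) - 1L)
      return(list(reference = r, query = query, truth = truth))
    }
    stop("could not build an unambiguous fixture in ", maxTries, " tries")
  })
}

#' @noRd
.countOccurrences <- function(s, pattern) {
  hits <- gregexpr(pattern, s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

# Idealized two-fragment model: a prefix [1..s] matches min(s, t) bases,
# a suffix [s+1..l] matches min(l - s, l - t) bases.  The model trace of
# the binary search (the former-part lengths it visits) is pure
# arithmetic in (l, t, threshold, minLength).
#' @noRd
.modelBinaryVisits <- function(l, t, threshold, minLength) {
  fl <- max(minLength, min(l %/% 2L, l - minLength))
  i <- 1L
  visited <- integer()
  repeat {
    visited <- c(visited, fl)
    rf <- min(fl, t) / fl
    rl <- min(l - fl, l - t) / (l - fl)
    if (rf > threshold && rl > threshold) break
    k <- l %/% 2^(i + 1)
    if (k == 0L) break
    nf <- if (rf >= rl) fl + k else fl - k
    if (nf < 1L || nf > l - 1L) break
    fl <- nf
    i <- i + 1L
  }
  visited
}

# True iff the split searches behave on this fixture exactly as on the
# idealized two-fragment model, for every threshold given: the whole-query
# ratio falls below the threshold, every split the model binary search
# visits gets the same two pass/fail decisions as in the model, and the
# incremental prefix scan crosses the threshold at the model position.
# Chance matches that flip none of these decisions are tolerated; any
# that would divert a search cause the placement to be resampled.
#' @noRd
.splitSearchConsistent <- function(query, r, t, thresholds, minLength,
                                   lk, scheme) {
  qc <- .encodeSeq(query, lk, "query")
  rc <- .encodeSeq(r, lk, "reference")
  l <- length(qc)
  pre <- .prefixScan(qc, rc, lk, scheme)[, 2L]
  suf <- .prefixScan(rev(qc), rev(rc), lk, scheme)[, 2L]
  for (th in thresholds) {
    if (pre[l] / l >= th) return(FALSE)
    if (t / l >= th) return(FALSE)
    for (fl in .modelBinaryVisits(l, t, th, minLength)) {
      if ((pre[fl] / fl > th) != (min(fl, t) / fl > th)) return(FALSE)
      j <- l - fl
      if ((suf[j] / j > th) != (min(j, l - t) / j > th)) return(FALSE)
    }
    Ls <- minLength:(l - 1L)
    below <- which(pmin(Ls, t) / Ls < th)
    Lstar <- if (length(below)) Ls[below[1L]] else max(Ls)
    for (L in minLength:Lstar) {
      if ((pre[L] / L < th) != (min(L, t) / L < th)) return(FALSE)
    }
  }
  TRUE
}

#' Benchmark the three deletion-position estimators on simulated queries
#'
#' For each query-length bin, \code{nPerBin} two-fragment queries are drawn
#' from the reference with [makeQuery()] and every requested method is run:
#' \code{"sw"} (classical whole-query alignment, [classicalSWBoundary()]),
#' \code{"incremental"} ([incrementalPartialAlign()]) and \code{"binary"}
#' ([binaryPartialAlign()]).  Each method's estimated deletion position is
#' compared with the truth by [edpe()]; for the split searches, a
#' \code{no_deletion} outcome falls back to the consumed-base estimate of
#' the whole-query alignment.  Per bin and method the mean and sample
#' standard deviation (n - 1 denominator; 0 when n = 1) of EDPE and of the
#' per-query wall-clock runtime are reported.
#'
#' @param reference reference sequence (character string).
#' @param bins list of inclusive length ranges, e.g.
#'   \code{list(c(100, 199), c(200, 299))}.
#' @param nPerBin queries per bin.
#' @param methods subset of \code{c("sw", "incremental", "binary")}.
#' @inheritParams incrementalPartialAlign
#' @inheritParams makeQuery
#' @param seed integer seed; the whole benchmark is reproducible from it.
#' @return list with \code{perQuery} (one row per query x method) and
#'   \code{stats} (one row per bin x method).
#' @seealso [writeBenchmark()] to serialise the result as TSV.
#' @export
runBenchmark <- function(reference,
                         bins = lapply(0:8, function(i)
                           c(100L + 100L * i, 199L + 100L * i)),
                         nPerBin = 100L,
                         methods = c("sw", "incremental", "binary"),
                         threshold = 0.9, minLength = 20L,
                         minFragment = 20L, minDeletion = 1000L,
                         mutationRate = 0, scheme = blosum62Scheme(),
                         seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  r <- .asSeqChar(reference, "reference")
  .withSeed(seed, {
    rows <- vector("list", length(bins) * nPerBin * length(methods))
    n <- 0L
    for (b in seq_along(bins)) {
      bin <- as.integer(bins[[b]])
      for (qi in seq_len(nPerBin)) {
        sim <- makeQuery(r, lengthRange = bin, minFragment = minFragment,
                         minDeletion = minDeletion,
                         mutationRate = mutationRate)
        truth <- sim$truth
        for (m in methods) {
          t0 <- proc.time()[["elapsed"]]
          if (m == "sw") {
            est <- classicalSWBoundary(sim$query, r, scheme)
            calls <- 1L
            status <- "sw"
          } else {
            res <- if (m == "incremental")
              incrementalPartialAlign(sim$query, r, threshold, minLength,
                                      scheme)
            else
              binaryPartialAlign(sim$query, r, threshold, minLength, scheme)
            est <- estimatedBoundary(res)
            calls <- swCalls(res)
            status <- res@status
          }
          n <- n + 1L
          rows[[n]] <- data.frame(
            bin = paste0(bin[1L], "-", bin[2L]), query = qi,
            query_length = nchar(sim$query),
            true_boundary = truth$true_boundary,
            true_deletion_length = truth$true_deletion_length,
            method = m, estimated_boundary = est,
            edpe = edpe(est, truth$true_boundary),
            sw_calls = calls, status = status,
            runtime_s = proc.time()[["elapsed"]] - t0)
        }
      }
    }
    perQuery <- do.call(rbind, rows[seq_len(n)])
    sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
    agg <- lapply(split(perQuery,
                        list(perQuery$bin, perQuery$method), drop = TRUE),
      function(d) data.frame(
        bin = d$bin[1L], method = d$method[1L], n = nrow(d),
        mean_edpe = mean(d$edpe), sd_edpe = sd0(d$edpe),
        mean_runtime_s = mean(d$runtime_s), sd_runtime_s = sd0(d$runtime_s),
        total_sw_calls = sum(d$sw_calls)))
    stats <- do.call(rbind, agg)
    stats <- stats[order(stats$bin, stats$method), ]
    rownames(stats) <- NULL
    list(perQuery = perQuery, stats = stats)
  })
}
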