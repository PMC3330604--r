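# FASTA handling and report writing for the command-line layer.

#' Read a multi-record FASTA file
#'
#' Records are returned as a named character vector; lowercase residues are
#' uppercased on load.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no sequence records in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence record in FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences as FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70 columns).
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be named")
  set <- Biostrings::BStringSet(toupper(x))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' @noRd
.writeTSV <- function(df, path, headerLines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(headerLines, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align each query record against a reference (report form)
#'
#' Runs [smithWaterman()] for every record of a query FASTA against the
#' single record of a reference FASTA and tabulates score, matches,
#' similarity ratio and the aligned intervals.  Input record order is
#' preserved.
#'
#' @param queryFasta,refFasta FASTA paths; the reference file must contain
#'   exactly one record.
#' @param scheme a [ScoringScheme-class].
#' @param out optional TSV output path.
#' @param pretty print each pairwise alignment to the console.
#' @return data frame with one row per query record.
#' @export
cmdAlign <- function(queryFasta, refFasta, scheme = blosum62Scheme(),
                     out = NULL, pretty = FALSE) {
  queries <- readFasta(queryFasta)
  refs <- readFasta(refFasta)
  if (length(refs) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(refs), ": ", refFasta)
  rows <- lapply(seq_along(queries), function(i) {
    aln <- smithWaterman(queries[[i]], refs[[1L]], scheme)
    if (pretty) {
      cat(">", names(queries)[i], "\n", sep = "")
      show(aln)
    }
    data.frame(query_id = names(queries)[i],
               query_length = nchar(queries[[i]]),
               score = aln@score, matches = aln@matches,
               similarity_ratio = similarityRatio(aln),
               query_start = aln@queryStart, query_end = aln@queryEnd,
               ref_start = aln@refStart, ref_end = aln@refEnd)
  })
  df <- do.call(rbind, rows)
  if (!is.null(out))
    .writeTSV(df, out, "# PartialAlign align report v1")
  invisible(df)
}

#' @noRd
.resultRow <- function(id, qlen, res) {
  if (methods::is(res, "PartialAlignmentResult")) {
    f <- res@former
    l <- res@latter
    data.frame(
      query_id = id, query_length = qlen, method = res@method,
      status = res@status, converged = res@converged,
      boundary = res@boundary,
      former_ref_start = if (is.null(f)) NA_integer_ else f@refStart,
      former_ref_end = if (is.null(f)) NA_integer_ else f@refEnd,
      latter_ref_start = if (is.null(l)) NA_integer_ else l@refStart,
      latter_ref_end = if (is.null(l)) NA_integer_ else l@refEnd,
      deletion_start = res@deletionStart, deletion_end = res@deletionEnd,
      deletion_length = res@deletionLength,
      former_ratio = if (is.null(f)) NA_real_ else similarityRatio(f),
      latter_ratio = if (is.null(l)) NA_real_ else similarityRatio(l),
      full_ratio = res@fullRatio, sw_calls = res@swCalls)
  } else {  # classical SW boundary (integer)
    data.frame(
      query_id = id, query_length = qlen, method = "sw",
      status = "sw", converged = TRUE, boundary = res,
      former_ref_start = NA_integer_, former_ref_end = NA_integer_,
      latter_ref_start = NA_integer_, latter_ref_end = NA_integer_,
      deletion_start = NA_integer_, deletion_end = NA_integer_,
      deletion_length = NA_integer_,
      former_ratio = NA_real_, latter_ratio = NA_real_,
      full_ratio = NA_real_, sw_calls = 1L)
  }
}

#' Locate a large deletion in each query record (report form)
#'
#' Runs the chosen boundary estimator for every record of a query FASTA.
#' A record that fails (for example a query shorter than twice
#' \code{minLength}) yields an error row and processing continues.
#'
#' @inheritParams cmdAlign
#' @param method \code{"binary"}, \code{"incremental"} or \code{"sw"} (the
#'   classical whole-query baseline, which reports a boundary but no
#'   deletion interval).
#' @param threshold,minLength split-search parameters, see
#'   [binaryPartialAlign()].
#' @param json optional path for a JSON report including the full split
#'   trace of each query.
#' @return data frame with one row per query record.
#' @export
cmdFindDeletion <- function(queryFasta, refFasta,
                            method = c("binary", "incremental", "sw"),
                            threshold = 0.9, minLength = 20L,
                            scheme = blosum62Scheme(), out = NULL,
                            json = NULL) {
  method <- match.arg(method)
  queries <- readFasta(queryFasta)
  refs <- readFasta(refFasta)
  if (length(refs) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(refs), ": ", refFasta)
  rows <- list()
  traces <- list()
  for (i in seq_along(queries)) {
    id <- names(queries)[i]
    qlen <- nchar(queries[[i]])
    res <- tryCatch({
      if (method == "sw")
        classicalSWBoundary(queries[[i]], refs[[1L]], scheme)
      else if (method == "incremental")
        incrementalPartialAlign(queries[[i]], refs[[1L]], threshold,
                                minLength, scheme)
      else
        binaryPartialAlign(queries[[i]], refs[[1L]], threshold, minLength,
                           scheme)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row <- .resultRow(id, qlen, NA_integer_)
      row$status <- "error"
      row$boundary <- NA_integer_
      row$method <- method
      rows[[i]] <- row
      traces[[i]] <- list(query_id = id, error = conditionMessage(res))
    } else {
      rows[[i]] <- .resultRow(id, qlen, res)
      traces[[i]] <- c(as.list(rows[[i]]),
        list(trace = if (methods::is(res, "PartialAlignmentResult"))
          res@trace else data.frame()))
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out))
    .writeTSV(df, out, "# PartialAlign find-deletion report v1")
  if (!is.null(json))
    jsonlite::write_json(traces, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  invisible(df)
}

#' Write benchmark results as TSV
#'
#' Serialises the output of [runBenchmark()]: a per-query table and a
#' per-bin summary table, each with a versioned header comment recording
#' the run parameters.  Runtime columns are excluded from the per-query
#' table by default so that identical seeds give byte-identical files.
#'
#' @param result list returned by [runBenchmark()].
#' @param perQueryPath,statsPath output paths (\code{NULL} to skip one).
#' @param params optional named list echoed into the header line.
#' @param includeRuntime keep the per-query runtime column.
#' @return invisibly, \code{result}.
#' @export
writeBenchmark <- function(result, perQueryPath = NULL, statsPath = NULL,
                           params = list(), includeRuntime = FALSE) {
  hdr <- "# PartialAlign benchmark v1"
  if (length(params))
    hdr <- c(hdr, paste0("# ", paste(names(params), unlist(params),
                                     sep = "=", collapse = " ")))
  if (!is.null(perQueryPath)) {
    pq <- result$perQuery
    if (!includeRuntime) pq$runtime_s <- NULL
    .writeTSV(pq, perQueryPath, hdr)
  }
  if (!is.null(statsPath))
    .writeTSV(result$stats, statsPath, hdr)
  invisible(result)
}
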