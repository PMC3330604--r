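# Shared fixtures and an independent alignment oracle.

b62 <- blosum62Scheme()
nuc <- nucleotideScheme()

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# Independent oracle for the optimal local alignment score: dynamic
# programme written straight from the cost definition, enumerating every
# gap-run length explicitly (no opening/extension state matrices).  Only
# usable for tiny inputs.
oracleScore <- function(q, r, scheme) {
  qs <- strsplit(q, "")[[1L]]
  rs <- strsplit(r, "")[[1L]]
  n <- length(qs); m <- length(rs)
  mat <- substitutionMatrix(scheme)
  open <- gapOpening(scheme); ext <- gapExtension(scheme)
  gapCost <- function(g) open + (g - 1) * ext
  H <- matrix(0, n + 1L, m + 1L)  # H[i+1, j+1]: best ending at (i, j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    v <- max(0, H[i, j] + mat[qs[i], rs[j]])
    for (g in seq_len(i - 1L)) v <- max(v, H[i + 1L - g, j + 1L] - gapCost(g))
    for (g in seq_len(j - 1L)) v <- max(v, H[i + 1L, j + 1L - g] - gapCost(g))
    H[i + 1L, j + 1L] <- v
  }
  max(H)
}

# Score of an alignment recomputed from its aligned strings (matrix scores
# minus affine gap costs), used to audit reported scores.
scoreFromStrings <- function(aq, ar, scheme) {
  mat <- substitutionMatrix(scheme)
  a <- strsplit(aq, "")[[1L]]
  b <- strsplit(ar, "")[[1L]]
  total <- 0
  lastGapSide <- ""  # a gap run continues only on the same sequence
  for (k in seq_along(a)) {
    side <- if (a[k] == "-") "q" else if (b[k] == "-") "r" else ""
    if (nzchar(side)) {
      total <- total - (if (side == lastGapSide) gapExtension(scheme)
                        else gapOpening(scheme))
    } else {
      total <- total + (if (a[k] == "N" || b[k] == "N") 0
                        else mat[a[k], b[k]])
    }
    lastGapSide <- side
  }
  total
}
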