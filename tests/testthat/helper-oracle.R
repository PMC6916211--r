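# Shared test helpers: random sequences/patterns and a brute-force
# spaced-word-match oracle that is independent of the package's C++
# matching path (pure R, chartr-based reverse complement).

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcOracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

randomPatternString <- function(len, weight) {
  stopifnot(weight >= 1L, len >= weight)
  m <- rep("0", len)
  m[1L] <- "1"
  if (weight > 1L) m[1L + sample(seq_len(len - 1L), weight - 1L)] <- "1"
  paste(m, collapse = "")
}

# All windows of s (0-based starts) whose full ell-window is N-free,
# with their spaced-word key.
.oracleWindows <- function(s, mask_chars, rec) {
  ell <- length(mask_chars)
  n <- nchar(s)
  if (n < ell) return(NULL)
  moff <- which(mask_chars == "1")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  starts <- 0:(n - ell)
  keys <- vapply(starts, function(p) {
    win <- chars[(p + 1L):(p + ell)]
    if (any(win == "N")) return(NA_character_)
    paste(win[moff], collapse = "")
  }, "")
  ok <- !is.na(keys)
  if (!any(ok)) return(NULL)
  data.frame(rec = rec, pos = starts[ok], key = keys[ok],
             stringsAsFactors = FALSE)
}

# Brute-force double loop over all window pairs and both orientations
# of setB; returns the same columns as enumerateMatches().
bruteForceMatches <- function(seqsA, seqsB, mask, scoreMat) {
  mc <- strsplit(mask, "", fixed = TRUE)[[1L]]
  ell <- length(mc)
  doff <- which(mc == "0")
  A <- do.call(rbind, lapply(seq_along(seqsA), function(i)
    .oracleWindows(seqsA[i], mc, i)))
  rows <- list()
  for (br in seq_along(seqsB)) {
    for (orient in c("forward", "reverse")) {
      s <- if (orient == "forward") seqsB[br] else rcOracle(seqsB[br])
      B <- .oracleWindows(s, mc, br)
      if (is.null(A) || is.null(B)) next
      hits <- merge(A, B, by = "key")
      if (nrow(hits) == 0L) next
      for (r in seq_len(nrow(hits))) {
        ap <- hits$pos.x[r]; bp <- hits$pos.y[r]
        a <- strsplit(substr(seqsA[hits$rec.x[r]], ap + 1L, ap + ell),
                      "", fixed = TRUE)[[1L]]
        b <- strsplit(substr(s, bp + 1L, bp + ell), "", fixed = TRUE)[[1L]]
        S <- sum(scoreMat[cbind(a[doff], b[doff])])
        m <- sum(a[doff] != b[doff])
        rows[[length(rows) + 1L]] <-
          data.frame(refRecord = hits$rec.x[r], refPos = ap,
                     qryRecord = br, qryPos = bp, strand = orient,
                     score = S, mismatches = m,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(refRecord = integer(0), refPos = integer(0),
                      qryRecord = integer(0), qryPos = integer(0),
                      strand = character(0), score = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Canonical row order for comparing match tables.
sortMatches <- function(df) {
  df <- df[, c("refRecord", "refPos", "qryRecord", "qryPos", "strand",
               "score", "mismatches")]
  df <- df[order(df$refRecord, df$refPos, df$qryRecord, df$qryPos,
                 df$strand), ]
  rownames(df) <- NULL
  df
}
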