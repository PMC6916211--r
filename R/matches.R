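#' Nucleotide substitution scores for don't-care positions
#'
#' The HOXD-derived DNA substitution matrix of Chiaromonte, Yap and
#' Miller (2002), the standard scoring for distinguishing homologous
#' from background spaced-word matches: positive scores on the
#' diagonal, transitions penalised less than transversions.
#'
#' @return symmetric 4x4 integer matrix with dimnames `A,C,G,T`.
#' @export
chiaromonteMatrix <- function() {
  m <- matrix(c( 91L, -114L,  -31L, -123L,
                -114L, 100L, -125L,  -31L,
                 -31L, -125L, 100L, -114L,
                -123L,  -31L, -114L,  91L),
              nrow = 4L, byrow = TRUE,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  m
}

#' Read a substitution matrix from a file
#'
#' Sixteen integers, whitespace-separated, row-major in `A,C,G,T`
#' order.
#'
#' @param path file with 16 integers.
#' @return 4x4 integer matrix with `A,C,G,T` dimnames.
#' @export
readScoreMatrix <- function(path) {
  vals <- scan(path, what = integer(), quiet = TRUE)
  if (length(vals) != 16L)
    stop("substitution matrix file must contain exactly 16 integers")
  matrix(as.integer(vals), nrow = 4L, byrow = TRUE,
         dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
}

.checkScoreMatrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4L))
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("substitution matrix must be symmetric")
  m
}

#' Extract the spaced words of one sequence
#'
#' One spaced word per window start `pos` in `[0, n - ell]` whose full
#' `ell`-length window is free of `N`; the word is the concatenation of
#' the nucleotides at the pattern's match positions.
#'
#' @param seq a character string (one sequence) over A/C/G/T/N.
#' @param pattern a [SpacedPattern].
#' @return data.frame with columns `key` (the weight-mer) and `pos`
#'   (0-based window start); zero rows when the sequence is shorter
#'   than the pattern.
#' @examples
#' extractSpacedWords("ACGTACG", spacedPattern("1100101"))
#' @export
extractSpacedWords <- function(seq, pattern) {
  stopifnot(is(pattern, "SpacedPattern"),
            is.character(seq), length(seq) == 1L)
  if (patternWeight(pattern) > 32L)
    stop("pattern weight must be <= 32")
  res <- cpp_extract_spaced_words(seq, matchOffsets(pattern),
                                  patternLength(pattern))
  data.frame(key = res$key, pos = res$pos, stringsAsFactors = FALSE)
}

#' Enumerate all spaced-word matches between two sequence sets
#'
#' Finds every pair of windows -- one from `setA` in forward
#' orientation, one from `setB` in forward or reverse-complement
#' orientation -- whose spaced words agree, and scores each match at
#' the pattern's don't-care positions.  For a reverse-strand match,
#' `qryPos` is the window start within the reverse-complemented record.
#' When `setA` and `setB` are the identical object, the trivial
#' self-pairs (same record, same position, forward) are excluded.
#'
#' @param setA,setB [SkimSeqSet] objects.
#' @param pattern a [SpacedPattern].
#' @param scoreMatrix 4x4 substitution matrix (default
#'   [chiaromonteMatrix()]).
#' @param maxBucket optional guard for pathological low-complexity
#'   inputs: spaced words occurring more than `maxBucket` times in
#'   `setA` are skipped (0 = unlimited, the default).
#' @return data.frame with one row per match: `refRecord`, `refPos`,
#'   `qryRecord`, `qryPos` (0-based), `strand`, `score` (don't-care
#'   score S), `mismatches` (m) and `dontcareN`.
#' @export
enumerateMatches <- function(setA, setB, pattern = defaultPattern(),
                             scoreMatrix = chiaromonteMatrix(),
                             maxBucket = 0L) {
  stopifnot(is(setA, "SkimSeqSet"), is(setB, "SkimSeqSet"),
            is(pattern, "SpacedPattern"))
  .checkScoreMatrix(scoreMatrix)
  if (patternWeight(pattern) > 32L)
    stop("pattern weight must be <= 32")
  if (length(sequences(setA)) == 0L || length(sequences(setB)) == 0L)
    stop("both sequence sets must be non-empty")
  # trivial self-pairs are excluded only for a genuine self-comparison
  # (same object); distinct taxa with identical sequences still match
  excl <- identical(setA, setB)
  df <- cpp_enumerate_matches(as.character(sequences(setA)),
                              as.character(sequences(setB)),
                              matchOffsets(pattern),
                              dontCareOffsets(pattern),
                              patternLength(pattern),
                              scoreMatrix, excl, as.integer(maxBucket))
  df$dontcareN <- rep.int(patternLength(pattern) - patternWeight(pattern),
                          nrow(df))
  df
}

#' Score one spaced-word match at the don't-care positions
#'
#' `S` is the sum of substitution scores over the aligned nucleotide
#' pairs at the don't-care positions, `m` the number of those pairs
#' that differ.  The match positions are assumed equal (that is what
#' makes the pair a spaced-word match) and do not contribute.
#'
#' @param segA,segB character strings of length `patternLength(pattern)`.
#' @param pattern a [SpacedPattern].
#' @param scoreMatrix 4x4 substitution matrix.
#' @return list with elements `S` (integer score) and `m` (mismatches).
#' @export
scoreMatch <- function(segA, segB, pattern, scoreMatrix = chiaromonteMatrix()) {
  stopifnot(is(pattern, "SpacedPattern"))
  ell <- patternLength(pattern)
  if (nchar(segA) != ell || nchar(segB) != ell)
    stop("segments must have the pattern length")
  .checkScoreMatrix(scoreMatrix)
  off <- dontCareOffsets(pattern) + 1L
  if (length(off) == 0L) return(list(S = 0L, m = 0L))
  a <- substring(segA, off, off)
  b <- substring(segB, off, off)
  list(S = sum(scoreMatrix[cbind(a, b)]), m = sum(a != b))
}

#' Filter spaced-word matches by their don't-care score
#'
#' Retains exactly the matches with score `S >= threshold`.  At the
#' default threshold 0, matches with a negative score are discarded and
#' matches scoring exactly 0 are kept.
#'
#' @param matches data.frame as returned by [enumerateMatches()].
#' @param threshold integer score threshold T.
#' @return the retained subset of `matches`.
#' @export
filterMatches <- function(matches, threshold = 0L) {
  matches[matches$score >= threshold, , drop = FALSE]
}
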