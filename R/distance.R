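#' Construct run parameters
#'
#' @param threshold integer score threshold T (default 0).
#' @param errorRate per-base sequencing error rate e (default 0.0024,
#'   the typical Illumina substitution-error rate).
#' @param mode comparison mode; `"auto"` (default) infers it from the
#'   roles of the two sequence sets.
#' @return a [SkimParams] object.
#' @export
skimParams <- function(threshold = 0L, errorRate = 0.0024,
                       mode = c("auto", "genome_vs_genome",
                                "genome_vs_reads", "reads_vs_reads")) {
  new("SkimParams", threshold = as.integer(threshold),
      errorRate = errorRate, mode = match.arg(mode))
}

.inferMode <- function(roleA, roleB) {
  nr <- sum(c(roleA, roleB) == "reads")
  c("genome_vs_genome", "genome_vs_reads", "reads_vs_reads")[nr + 1L]
}

#' Pooled mismatch frequency over retained matches
#'
#' The average number of mismatches per position over *all* don't-care
#' positions of the retained spaced-word matches, computed by pooled
#' counting: total mismatches divided by total don't-care positions
#' (not a per-match average, which would differ if matches mixed
#' patterns of different weight).
#'
#' @param matches data.frame of retained matches (columns `mismatches`
#'   and `dontcareN`).
#' @return list with `pRaw`, `totalMismatch`, `totalDontCare`,
#'   `nMatches`; `pRaw` is `NA` when no matches were retained.
#' @export
estimateP <- function(matches) {
  n <- nrow(matches)
  tm <- sum(as.numeric(matches$mismatches))
  td <- sum(as.numeric(matches$dontcareN))
  list(pRaw = if (n > 0L && td > 0) tm / td else NA_real_,
       totalMismatch = tm, totalDontCare = td, nMatches = n)
}

.effectiveError <- function(mode, e) {
  switch(mode,
         genome_vs_genome = 0,
         genome_vs_reads  = e,
         reads_vs_reads   = 2 * e - (4 / 3) * e^2,
         stop("unknown mode: ", mode))
}

#' Correct an observed mismatch frequency for sequencing error
#'
#' Sequencing error is modelled as a uniform substitution channel: each
#' base is misread to one of the three other bases with total
#' probability `e`.  One such channel sits between a read set and the
#' truth, so the effective error is `e` for genome-vs-reads, the
#' composition of two channels `2e - (4/3)e^2` for reads-vs-reads, and
#' 0 for genome-vs-genome.  Inverting the channel gives
#' `p = (pRaw - eHat) / (1 - (4/3) eHat)`, clamped below at 0.
#'
#' @param pRaw observed (pooled) mismatch frequency in `[0, 1]`.
#' @param mode comparison mode (see [skimParams()]).
#' @param errorRate per-base error rate e.
#' @return the corrected mismatch frequency.
#' @export
correctError <- function(pRaw, mode, errorRate = 0.0024) {
  eHat <- .effectiveError(mode, errorRate)
  pmax(0, (pRaw - eHat) / (1 - (4 / 3) * eHat))
}

#' Jukes-Cantor distance from a mismatch frequency
#'
#' `d = -(3/4) log(1 - (4/3) p)`, the expected number of substitutions
#' per position under the Jukes-Cantor model given a mismatch fraction
#' `p`.  Saturated inputs (`p >= 0.75`) return `NA`: the distance is
#' undefined there, not infinite.
#'
#' @param p mismatch frequency (vectorised).
#' @return Jukes-Cantor distance(s), `NA` where `p >= 0.75`.
#' @seealso [pOfD()] for the inverse (the forward channel).
#' @export
jukesCantor <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < 0.75
  out[ok] <- -0.75 * log1p(-(4 / 3) * p[ok])
  out
}

#' Expected mismatch frequency at a given Jukes-Cantor distance
#'
#' The forward Jukes-Cantor channel `p = (3/4)(1 - exp(-(4/3) d))`;
#' exact inverse of [jukesCantor()].
#'
#' @param d distance in substitutions per position (vectorised).
#' @return expected mismatch fraction in `[0, 0.75)`.
#' @export
pOfD <- function(d) 0.75 * (1 - exp(-(4 / 3) * d))

.makeEstimate <- function(stats, mode, errorRate) {
  if (stats$nMatches < 1L) {
    return(new("DistanceEstimate", nMatches = 0L,
               totalDontCare = stats$totalDontCare,
               totalMismatch = stats$totalMismatch,
               pRaw = NA_real_, pCorrected = NA_real_,
               distance = NA_real_, defined = FALSE,
               reason = "no spaced-word matches", mode = mode))
  }
  pc <- correctError(stats$pRaw, mode, errorRate)
  if (pc >= 0.75) {
    return(new("DistanceEstimate", nMatches = as.integer(stats$nMatches),
               totalDontCare = stats$totalDontCare,
               totalMismatch = stats$totalMismatch,
               pRaw = stats$pRaw, pCorrected = pc,
               distance = NA_real_, defined = FALSE,
               reason = "saturated", mode = mode))
  }
  new("DistanceEstimate", nMatches = as.integer(stats$nMatches),
      totalDontCare = stats$totalDontCare,
      totalMismatch = stats$totalMismatch,
      pRaw = stats$pRaw, pCorrected = pc,
      distance = jukesCantor(pc), defined = TRUE, reason = "", mode = mode)
}

#' Estimate the Jukes-Cantor distance between two sequence sets
#'
#' The full pipeline: enumerate all spaced-word matches between the two
#' sets (both strands), discard matches whose don't-care score falls
#' below the threshold, pool the mismatch counts over the retained
#' matches, correct for sequencing error according to the comparison
#' mode, and apply the Jukes-Cantor correction.  When no match is
#' retained, or the corrected mismatch frequency saturates the model,
#' the estimate is flagged undefined rather than raising an error.
#'
#' @param setA,setB [SkimSeqSet] objects (assembled genome/contigs or
#'   unassembled reads, see [readSeqSet()]).
#' @param pattern a [SpacedPattern] (default: the shipped 72/12
#'   pattern).
#' @param scoreMatrix 4x4 substitution matrix (default
#'   [chiaromonteMatrix()]).
#' @param params a [SkimParams]; with mode `"auto"` the mode is
#'   inferred from the two sets' roles.
#' @param maxBucket see [enumerateMatches()].
#' @return a [DistanceEstimate].
#' @examples
#' g <- randomGenome(20000, seed = 1)
#' r <- simulateReads(g, coverage = 1, errorRate = 0, seed = 2)
#' jcDistance(estimateDistance(g, r))  # ~0: reads come from g itself
#' @export
estimateDistance <- function(setA, setB, pattern = defaultPattern(),
                             scoreMatrix = chiaromonteMatrix(),
                             params = skimParams(), maxBucket = 0L) {
  stopifnot(is(params, "SkimParams"))
  mode <- params@mode
  if (mode == "auto") mode <- .inferMode(seqRole(setA), seqRole(setB))
  matches <- enumerateMatches(setA, setB, pattern, scoreMatrix, maxBucket)
  kept <- filterMatches(matches, params@threshold)
  .makeEstimate(estimateP(kept), mode, params@errorRate)
}

#' Split a genome into equal fragments overlapping by the seed span
#'
#' Fragment boundaries are chosen so that every `ell`-length window of
#' the genome lies in exactly one fragment: with core length
#' `k = floor((G - (ell - 1)) / nFragments)`, fragment `i` covers
#' positions `[i k, i k + k + ell - 2]` (0-based) and the final
#' fragment absorbs the remainder, so neighbouring fragments overlap by
#' `ell - 1`.
#'
#' @param seq single character string (the genome or one contig).
#' @param nFragments number of fragments.
#' @param ell pattern length.
#' @return data.frame with 1-based `start`/`end` columns, one row per
#'   fragment.
#' @export
fragmentBounds <- function(seq, nFragments, ell) {
  G <- nchar(seq)
  if (G < nFragments + ell)
    stop("genome too short to split into ", nFragments, " fragments")
  k <- (G - (ell - 1L)) %/% nFragments
  start0 <- (seq_len(nFragments) - 1L) * k
  end0 <- start0 + k + ell - 2L
  end0[nFragments] <- G - 1L
  data.frame(start = start0 + 1L, end = end0 + 1L)
}

#' Bias-mitigated distance via genome fragmentation
#'
#' Whole-genome spaced-word comparison finds more matches per position
#' in highly similar regions, which over-weights those regions and
#' under-estimates the distance.  This mode splits `genomeA` into
#' `nFragments` equal-length fragments (neighbouring fragments overlap
#' by pattern length minus one, so every seed window lies in exactly
#' one fragment), estimates a distance per fragment against the full
#' `genomeB`, and reports the unweighted mean over the fragments with a
#' defined estimate.  Multi-contig genomes are fragmented per contig,
#' with the fragment budget apportioned by contig length.
#'
#' @inheritParams estimateDistance
#' @param genomeA,genomeB [SkimSeqSet] objects with role `"genome"`.
#' @param nFragments total number of fragments (default 2000).
#' @return a [FragmentedEstimate].
#' @export
fragmentedDistance <- function(genomeA, genomeB, pattern = defaultPattern(),
                               scoreMatrix = chiaromonteMatrix(),
                               params = skimParams(), nFragments = 2000L) {
  stopifnot(is(genomeA, "SkimSeqSet"), is(genomeB, "SkimSeqSet"))
  if (seqRole(genomeA) != "genome" || seqRole(genomeB) != "genome")
    stop("fragmented mode compares two assembled genomes")
  ell <- patternLength(pattern)
  contigs <- as.character(sequences(genomeA))
  lens <- nchar(contigs)
  nFragments <- as.integer(nFragments)
  # apportion fragments by contig length, at least one per contig
  nf <- if (length(contigs) == 1L) nFragments else {
    raw <- pmax(1L, as.integer(round(nFragments * lens / sum(lens))))
    raw
  }
  frags <- character(0)
  bounds <- list()
  for (i in seq_along(contigs)) {
    b <- fragmentBounds(contigs[i], nf[i], ell)
    frags <- c(frags, substring(contigs[i], b$start, b$end))
    bounds[[i]] <- cbind(contig = i, b)
  }
  bounds <- do.call(rbind, bounds)
  params@mode <- "genome_vs_genome"
  ests <- lapply(seq_along(frags), function(i) {
    fs <- skimSeqSet(setNames(frags[i], "fragment"),
                     taxon = taxonLabel(genomeA), role = "genome")
    estimateDistance(fs, genomeB, pattern, scoreMatrix, params)
  })
  d <- vapply(ests, jcDistance, numeric(1))
  per <- data.frame(contig = bounds$contig, start = bounds$start,
                    end = bounds$end,
                    nMatches = vapply(ests, nMatches, integer(1)),
                    distance = d)
  nUndef <- sum(is.na(d))
  new("FragmentedEstimate",
      distance = if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE),
      perFragment = per,
      nFragments = length(frags),
      nUndefined = as.integer(nUndef),
      defined = !all(is.na(d)))
}

#' @rdname skimdist-accessors
#' @export
setMethod("isDefined", "DistanceEstimate", function(x) x@defined)

#' @rdname skimdist-accessors
#' @export
setMethod("nMatches", "DistanceEstimate", function(x) x@nMatches)

#' @rdname skimdist-accessors
#' @export
setMethod("rawMismatchRate", "DistanceEstimate", function(x) x@pRaw)

#' @rdname skimdist-accessors
#' @export
setMethod("correctedMismatchRate", "DistanceEstimate",
          function(x) x@pCorrected)

#' @rdname skimdist-accessors
#' @export
setMethod("jcDistance", "DistanceEstimate", function(x) x@distance)

#' @rdname skimdist-accessors
#' @export
setMethod("undefinedReason", "DistanceEstimate", function(x) x@reason)

#' @rdname skimdist-accessors
#' @export
setMethod("isDefined", "FragmentedEstimate", function(x) x@defined)

#' @rdname skimdist-accessors
#' @export
setMethod("jcDistance", "FragmentedEstimate", function(x) x@distance)

setMethod("show", "DistanceEstimate", function(object) {
  cat("DistanceEstimate (", object@mode, ")\n", sep = "")
  cat("  matches: ", object@nMatches, "\n", sep = "")
  if (object@defined) {
    cat(sprintf("  p_raw = %.6f, p_corrected = %.6f, d = %.6f\n",
                object@pRaw, object@pCorrected, object@distance))
  } else {
    cat("  undefined: ", object@reason, "\n", sep = "")
  }
})

setMethod("show", "FragmentedEstimate", function(object) {
  cat("FragmentedEstimate over ", object@nFragments, " fragments (",
      object@nUndefined, " undefined)\n", sep = "")
  if (object@defined)
    cat(sprintf("  mean d = %.6f\n", object@distance))
  else cat("  undefined on every fragment\n")
})
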