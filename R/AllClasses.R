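#' Binary spaced-seed pattern
#'
#' A pattern over match positions (`1`) and don't-care positions (`0`).
#' Spaced words are read off at the match positions of a length-`ell`
#' window; don't-care positions may mismatch and are where mismatch
#' frequencies are sampled.  Patterns must start with `1` so that the
#' pattern length equals the span of the seed.
#'
#' @slot mask single character string over `{"0","1"}`.
#' @seealso [spacedPattern()], [defaultPattern()]
#' @export
setClass("SpacedPattern", representation(mask = "character"))

setValidity("SpacedPattern", function(object) {
  m <- object@mask
  if (length(m) != 1L || is.na(m) || nchar(m) == 0L)
    return("mask must be one non-empty string")
  ch <- strsplit(m, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("0", "1")))
    return("mask may contain only '0' and '1'")
  if (ch[1L] != "1")
    return("pattern must start with a match position ('1')")
  if (!any(ch == "1"))
    return("pattern needs at least one match position")
  TRUE
})

#' Tagged set of sequences for one taxon
#'
#' Wraps a [Biostrings::DNAStringSet] with a taxon label and a role:
#' `"genome"` for assembled genomes or contigs, `"reads"` for
#' unassembled sequencing reads.  Sequences are normalised on
#' construction (uppercase; anything outside A/C/G/T becomes N).
#'
#' @slot sequences [Biostrings::DNAStringSet] of the records.
#' @slot taxon single character taxon label.
#' @slot role `"genome"` or `"reads"`.
#' @seealso [skimSeqSet()], [readSeqSet()]
#' @export
setClass("SkimSeqSet",
         representation(sequences = "DNAStringSet",
                        taxon = "character",
                        role = "character"))

setValidity("SkimSeqSet", function(object) {
  if (length(object@taxon) != 1L || is.na(object@taxon) ||
      !nzchar(object@taxon))
    return("taxon must be one non-empty string")
  if (length(object@role) != 1L || !object@role %in% c("genome", "reads"))
    return("role must be 'genome' or 'reads'")
  nm <- names(object@sequences)
  if (length(object@sequences) > 0L &&
      (is.null(nm) || any(!nzchar(nm)) || anyNA(nm)))
    return("all records need non-empty ids")
  TRUE
})

#' Run parameters for distance estimation
#'
#' @slot threshold integer score threshold T; spaced-word matches with
#'   don't-care score below `threshold` are discarded (default 0, i.e.
#'   only negative scores are discarded).
#' @slot errorRate per-base sequencing error rate e used for the error
#'   correction (default 0.0024, the typical Illumina rate).
#' @slot mode one of `"auto"`, `"genome_vs_genome"`, `"genome_vs_reads"`,
#'   `"reads_vs_reads"`; `"auto"` infers the mode from the roles of the
#'   two input sets.
#' @seealso [skimParams()]
#' @export
setClass("SkimParams",
         representation(threshold = "integer",
                        errorRate = "numeric",
                        mode = "character"))

setValidity("SkimParams", function(object) {
  if (length(object@threshold) != 1L || is.na(object@threshold))
    return("threshold must be one integer")
  e <- object@errorRate
  if (length(e) != 1L || is.na(e) || e < 0 || e >= 0.75)
    return("errorRate must be in [0, 0.75)")
  if (length(object@mode) != 1L ||
      !object@mode %in% c("auto", "genome_vs_genome", "genome_vs_reads",
                          "reads_vs_reads"))
    return("unknown mode")
  TRUE
})

#' Result of a pairwise distance estimation
#'
#' Pooled mismatch statistics over the retained spaced-word matches,
#' the error-corrected mismatch frequency and the Jukes-Cantor
#' distance.  An estimate is *defined* iff at least one match was
#' retained and the corrected mismatch frequency is below 3/4 (the
#' Jukes-Cantor saturation point); otherwise `distance` is `NA` and
#' `reason` records why.
#'
#' @slot nMatches number of retained spaced-word matches.
#' @slot totalDontCare total don't-care positions over retained matches.
#' @slot totalMismatch total mismatches at those positions.
#' @slot pRaw pooled mismatch frequency `totalMismatch/totalDontCare`.
#' @slot pCorrected mismatch frequency after sequencing-error correction.
#' @slot distance Jukes-Cantor distance (substitutions per position),
#'   `NA` when undefined.
#' @slot defined logical definedness flag.
#' @slot reason `""`, `"no spaced-word matches"`, or `"saturated"`.
#' @slot mode the comparison mode that was used.
#' @export
setClass("DistanceEstimate",
         representation(nMatches = "integer",
                        totalDontCare = "numeric",
                        totalMismatch = "numeric",
                        pRaw = "numeric",
                        pCorrected = "numeric",
                        distance = "numeric",
                        defined = "logical",
                        reason = "character",
                        mode = "character"))

#' Result of a fragmented genome-vs-genome comparison
#'
#' One genome is split into equal-length fragments overlapping by
#' pattern length minus one; each fragment is compared to the full
#' second genome and the per-fragment Jukes-Cantor distances are
#' averaged (undefined fragments are excluded from the mean and
#' counted).
#'
#' @slot distance mean distance over defined fragments (`NA` if none).
#' @slot perFragment data.frame with one row per fragment (start, end,
#'   nMatches, distance).
#' @slot nFragments number of fragments used.
#' @slot nUndefined number of fragments with undefined estimates.
#' @slot defined `TRUE` iff at least one fragment was defined.
#' @export
setClass("FragmentedEstimate",
         representation(distance = "numeric",
                        perFragment = "data.frame",
                        nFragments = "integer",
                        nUndefined = "integer",
                        defined = "logical"))
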