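# Benchmark data generation: random genomes, Jukes-Cantor evolution
# with indels, Illumina-like single-end reads, and evolution along a
# known tree.  All generators are deterministic given their seed and
# restore the caller's RNG state.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.BASES <- c("A", "C", "G", "T")

.codesToString <- function(codes) {
  # codes in 0..3
  paste(.BASES[codes + 1L], collapse = "")
}

.stringToCodes <- function(s) {
  codes <- match(strsplit(s, "", fixed = TRUE)[[1L]], .BASES) - 1L
  if (anyNA(codes)) stop("sequence must be over A/C/G/T")
  codes
}

#' Generate a uniform random genome
#'
#' An i.i.d. uniform A/C/G/T sequence, the synthetic stand-in for a
#' real bacterial genome in the benchmark scenarios.
#'
#' @param length genome length in bp.
#' @param seed RNG seed; identical seeds give identical genomes.  The
#'   caller's RNG state is preserved.
#' @param taxon taxon label (default `"genome"`).
#' @return a [SkimSeqSet] with one record and role `"genome"`.
#' @export
randomGenome <- function(length, seed = NULL, taxon = "genome") {
  stopifnot(length > 0)
  s <- .withSeed(seed, .codesToString(sample.int(4L, length, replace = TRUE) - 1L))
  skimSeqSet(setNames(s, taxon), taxon = taxon, role = "genome")
}

#' Evolve a genome under the Jukes-Cantor model with indels
#'
#' Each position is substituted independently with probability
#' `pOfD(dTrue)` -- the Jukes-Cantor channel, so that the expected
#' estimable distance equals `dTrue` -- to a uniformly chosen different
#' base.  Independently, an indel event occurs at each position with
#' probability `indelProb`; event lengths are uniform on
#' `indelLen[1]..indelLen[2]`, and each event is an insertion (i.i.d.
#' uniform bases, placed immediately before the position) or a deletion
#' with probability `insertionFraction` / `1 - insertionFraction`.  All
#' events are drawn against the original coordinate system and applied
#' right to left, so multiple events have well-defined semantics.
#'
#' @param genome a [SkimSeqSet] with a single N-free record, or a
#'   character string.
#' @param dTrue target Jukes-Cantor distance (substitutions per
#'   position).
#' @param indelProb per-position indel event probability (default 0.01;
#'   set 0 for substitutions only).
#' @param indelLen length-2 integer vector, uniform indel length range
#'   (default `c(1, 100)`).
#' @param insertionFraction probability that an event is an insertion
#'   (default 0.5).
#' @param seed RNG seed.
#' @param taxon taxon label of the evolved genome.
#' @return a [SkimSeqSet] (role `"genome"`) with attribute
#'   `"groundTruth"`: a list with `dTrue`, `nSubstituted`,
#'   `nInsertions`, `nDeletions` and `seed`.
#' @export
evolveGenome <- function(genome, dTrue, indelProb = 0.01,
                         indelLen = c(1L, 100L), insertionFraction = 0.5,
                         seed = NULL, taxon = "evolved") {
  s <- if (is(genome, "SkimSeqSet")) {
    stopifnot(length(sequences(genome)) == 1L)
    as.character(sequences(genome))[1L]
  } else genome
  stopifnot(dTrue >= 0, indelProb >= 0, indelProb < 1,
            indelLen[1] >= 1, indelLen[1] <= indelLen[2])
  codes <- .stringToCodes(s)
  n <- length(codes)
  res <- .withSeed(seed, {
    pSub <- pOfD(dTrue)
    subMask <- runif(n) < pSub
    nSub <- sum(subMask)
    if (nSub > 0) {
      # uniformly one of the three other bases
      codes[subMask] <- (codes[subMask] +
                           sample.int(3L, nSub, replace = TRUE)) %% 4L
    }
    nIns <- 0L; nDel <- 0L
    if (indelProb > 0) {
      at <- which(runif(n) < indelProb)
      k <- length(at)
      if (k > 0) {
        lens <- sample.int(indelLen[2] - indelLen[1] + 1L, k,
                           replace = TRUE) + indelLen[1] - 1L
        isIns <- runif(k) < insertionFraction
        nIns <- sum(isIns); nDel <- k - nIns
        keep <- rep(TRUE, n)
        del <- which(!isIns)
        for (i in del) {
          to <- min(n, at[i] + lens[i] - 1L)
          keep[at[i]:to] <- FALSE
        }
        insAt <- at[isIns]
        insLen <- lens[isIns]
        # draw inserted bases in event order for reproducibility
        insSeq <- lapply(insLen, function(L)
          sample.int(4L, L, replace = TRUE) - 1L)
        # assemble: kept bases of each gap between insertion points,
        # interleaved with the inserted blocks
        ord <- order(insAt)
        insAt <- insAt[ord]; insSeq <- insSeq[ord]
        bnd <- c(0L, insAt - 1L, n)  # insertions go before position insAt
        pieces <- vector("list", 2L * length(insAt) + 1L)
        for (i in seq_along(insAt)) {
          lo <- bnd[i] + 1L; hi <- bnd[i + 1L]
          pieces[[2L * i - 1L]] <- if (lo <= hi)
            codes[lo:hi][keep[lo:hi]] else integer(0)
          pieces[[2L * i]] <- insSeq[[i]]
        }
        lo <- bnd[length(insAt) + 1L] + 1L
        pieces[[2L * length(insAt) + 1L]] <- if (lo <= n)
          codes[lo:n][keep[lo:n]] else integer(0)
        codes <- unlist(pieces, use.names = FALSE)
      }
    }
    list(codes = codes, nSub = nSub, nIns = nIns, nDel = nDel)
  })
  out <- skimSeqSet(setNames(.codesToString(res$codes), taxon),
                    taxon = taxon, role = "genome")
  attr(out, "groundTruth") <- list(dTrue = dTrue, nSubstituted = res$nSub,
                                   nInsertions = res$nIns,
                                   nDeletions = res$nDel, seed = seed)
  out
}

#' Simulate Illumina-like single-end reads
#'
#' `round(coverage * G / readLength)` reads of fixed length are drawn
#' with uniform start positions and uniform strand; each base is then
#' misread independently with probability `errorRate` to a uniformly
#' chosen different base (the magnitude of typical Illumina
#' substitution error; read-level indel errors and quality profiles are
#' not modelled).
#'
#' @param genome a [SkimSeqSet] with a single record, or a character
#'   string, of length at least `readLength`.
#' @param coverage target coverage c (total read bases / genome
#'   length), e.g. `2^-6`.
#' @param readLength read length L in bp (default 150).
#' @param errorRate per-base substitution error rate (default 0.0024).
#' @param seed RNG seed.
#' @param taxon taxon label for the read set.
#' @return a [SkimSeqSet] with role `"reads"`, reads named `read1..n`.
#' @export
simulateReads <- function(genome, coverage, readLength = 150L,
                          errorRate = 0.0024, seed = NULL,
                          taxon = "reads") {
  s <- if (is(genome, "SkimSeqSet")) {
    stopifnot(length(sequences(genome)) == 1L)
    as.character(sequences(genome))[1L]
  } else genome
  G <- nchar(s)
  if (G < readLength) stop("genome shorter than the read length")
  stopifnot(coverage > 0, errorRate >= 0, errorRate < 1)
  nReads <- max(0L, as.integer(round(coverage * G / readLength)))
  reads <- .withSeed(seed, {
    starts <- sample.int(G - readLength + 1L, nReads, replace = TRUE)
    rev <- runif(nReads) < 0.5
    r <- substring(s, starts, starts + readLength - 1L)
    if (any(rev)) r[rev] <- revComp(r[rev])
    if (errorRate > 0 && nReads > 0) {
      hit <- which(runif(nReads * readLength) < errorRate)
      for (h in hit) {
        i <- (h - 1L) %/% readLength + 1L
        j <- (h - 1L) %% readLength + 1L
        old <- match(substr(r[i], j, j), .BASES) - 1L
        newb <- (old + sample.int(3L, 1L)) %% 4L
        substr(r[i], j, j) <- .BASES[newb + 1L]
      }
    }
    r
  })
  names(reads) <- if (nReads > 0) paste0("read", seq_len(nReads))
                  else character(0)
  skimSeqSet(reads, taxon = taxon, role = "reads")
}

#' Evolve a root genome along a phylogenetic tree
#'
#' Recursively applies [evolveGenome()] along every branch, with the
#' branch length as the Jukes-Cantor distance, starting from the given
#' root genome.  Indels are off by default so that leaf-to-leaf
#' distances stay additive under the substitution channel.
#'
#' @param root a [SkimSeqSet] with a single record (the ancestral
#'   genome).
#' @param tree a rooted `ape::phylo` tree with non-negative branch
#'   lengths.
#' @param indelProb per-position indel probability applied on every
#'   branch (default 0).
#' @param seed base RNG seed; per-branch seeds are derived from it
#'   deterministically.
#' @return named list of [SkimSeqSet] objects, one per leaf label.
#' @export
evolveAlongTree <- function(root, tree, indelProb = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0))
  nTip <- length(tree$tip.label)
  rootNode <- nTip + 1L
  genomes <- vector("list", nTip + tree$Nnode)
  genomes[[rootNode]] <- root
  out <- list()
  edgeSeed <- function(i) if (is.null(seed)) NULL else seed + i
  # edges in preorder: parents always appear before their children
  ord <- order(tree$edge[, 1L])
  pending <- tree$edge[ord, , drop = FALSE]
  lens <- tree$edge.length[ord]
  done <- rep(FALSE, nrow(pending))
  while (!all(done)) {
    progressed <- FALSE
    for (i in which(!done)) {
      par <- pending[i, 1L]; child <- pending[i, 2L]
      if (is.null(genomes[[par]])) next
      lab <- if (child <= nTip) tree$tip.label[child]
             else paste0("node", child)
      genomes[[child]] <- evolveGenome(genomes[[par]], dTrue = lens[i],
                                       indelProb = indelProb,
                                       seed = edgeSeed(i), taxon = lab)
      done[i] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) stop("tree edges do not connect to the root")
  }
  for (t in seq_len(nTip)) out[[tree$tip.label[t]]] <- genomes[[t]]
  out
}
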