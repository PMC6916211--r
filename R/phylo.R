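#' All-pairs distance matrix over a list of taxa
#'
#' Runs [estimateDistance()] for every pair of taxa.  The comparison
#' mode of each pair is inferred from the two roles (two genomes ->
#' genome-vs-genome, one read set -> genome-vs-reads, two read sets ->
#' reads-vs-reads).  Undefined pairs are recorded as `NA`; any `NA`
#' blocks tree building in [neighborJoining()].
#'
#' @param taxa list of [SkimSeqSet] objects with unique taxon labels.
#' @inheritParams estimateDistance
#' @return symmetric numeric matrix with zero diagonal, taxon labels as
#'   dimnames, and `NA` for undefined pairs.
#' @export
buildDistanceMatrix <- function(taxa, pattern = defaultPattern(),
                                scoreMatrix = chiaromonteMatrix(),
                                params = skimParams()) {
  stopifnot(is.list(taxa), length(taxa) >= 2L)
  labels <- vapply(taxa, taxonLabel, "")
  if (anyDuplicated(labels))
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      est <- estimateDistance(taxa[[i]], taxa[[j]], pattern, scoreMatrix,
                              params)
      D[i, j] <- D[j, i] <- jcDistance(est)
    }
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei Neighbor-Joining (the agglomerative algorithm that
#' repeatedly joins the pair minimising the Q-criterion), as
#' implemented in \pkg{ape}.  NJ is exact on additive matrices:
#' it recovers the generating topology and branch lengths.  Negative
#' branch lengths, which classic NJ can produce on noisy input, are
#' kept by default.
#'
#' @param D symmetric numeric distance matrix with taxon labels as
#'   dimnames, zero diagonal, no `NA` entries, at least 3 taxa.
#' @param clampNegative if `TRUE`, negative branch lengths are set
#'   to 0.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighborJoining <- function(D, clampNegative = FALSE) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3L) stop("Neighbor-Joining needs at least 3 taxa")
  if (anyNA(D))
    stop("distance matrix has undefined entries; cannot build a tree")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  tree <- ape::nj(D)
  if (clampNegative) tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Write / read Newick trees
#'
#' Thin wrappers around \pkg{ape}'s Newick serialisation, kept here so
#' the package's file interfaces live in one place.
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @return `writeNewick()` returns `path` invisibly; `readNewick()`
#'   returns an `ape::phylo`.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
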