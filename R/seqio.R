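.normalizeDNA <- function(x) {
  # uppercase, then collapse everything outside A/C/G/T to N
  nm <- names(x)
  out <- gsub("[^ACGT]", "N", toupper(as.character(x)), perl = TRUE)
  names(out) <- nm
  out
}

#' Construct a sequence set from character vectors
#'
#' @param seqs named character vector (or [Biostrings::DNAStringSet]) of
#'   sequences; unnamed vectors get `seq1`, `seq2`, ... ids.
#' @param taxon taxon label for the whole set.
#' @param role `"genome"` or `"reads"`.
#' @return a [SkimSeqSet] with normalised sequences (uppercase,
#'   non-ACGT characters replaced by `N`).
#' @export
skimSeqSet <- function(seqs, taxon, role = c("genome", "reads")) {
  role <- match.arg(role)
  seqs <- .normalizeDNA(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  new("SkimSeqSet", sequences = Biostrings::DNAStringSet(seqs),
      taxon = taxon, role = role)
}

#' Read a FASTA or FASTQ file into a sequence set
#'
#' One file per taxon.  The format is detected from the first character
#' of the file (`>` FASTA, `@` FASTQ); gzip-compressed files are
#' accepted.  FASTQ qualities are parsed and discarded: the sequencing
#' error model used downstream is a global per-base rate, not a
#' per-base quality weighting.  Sequences are uppercased and characters
#' outside A/C/G/T (ambiguity codes etc.) become `N`.
#'
#' @param path path to a FASTA or FASTQ file, optionally `.gz`.
#' @param role `"genome"` or `"reads"`.
#' @param taxon taxon label; defaults to the file name without
#'   extensions.
#' @return a [SkimSeqSet].
#' @export
readSeqSet <- function(path, role = c("genome", "reads"), taxon = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L) stop("empty file: ", path)
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot detect FASTA/FASTQ format of ", path)
  if (fmt == "fasta") {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
  } else {
    # validate the 4-line record structure before parsing; qualities
    # are checked for length and then discarded
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    lines <- tryCatch(readLines(con), finally = close(con))
    if (length(lines) %% 4L != 0L)
      stop("malformed FASTQ (truncated record) in ", path)
    sq <- lines[seq.int(2L, length(lines), by = 4L)]
    qu <- lines[seq.int(4L, length(lines), by = 4L)]
    if (any(nchar(sq) != nchar(qu)))
      stop("malformed FASTQ: sequence/quality length mismatch in ", path)
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  }
  if (length(ss) == 0L) stop("no records in ", path)
  seqs <- .normalizeDNA(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(taxon)) taxon <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                                   basename(path))
  new("SkimSeqSet", sequences = Biostrings::DNAStringSet(seqs),
      taxon = taxon, role = role)
}

#' Write a sequence set to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality character (`I`), matching
#' the package's global-error-rate model in which per-base qualities
#' are uninformative.
#'
#' @param x a [SkimSeqSet].
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
writeSeqSet <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is(x, "SkimSeqSet"))
  if (format == "fasta") {
    Biostrings::writeXStringSet(sequences(x), filepath = path)
  } else {
    s <- as.character(sequences(x))
    lines <- rbind(paste0("@", names(s)), s, "+",
                   vapply(nchar(s), function(n) strrep("I", n), ""))
    writeLines(as.vector(lines), path)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector of sequences over A/C/G/T/N.
#' @return the reverse-complemented sequences (`A<->T`, `C<->G`, `N`
#'   fixed).  An involution: `revComp(revComp(x)) == x`.
#' @export
revComp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("revComp: sequences must be over A/C/G/T/N")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' @rdname skimdist-accessors
#' @export
setMethod("sequences", "SkimSeqSet", function(x) x@sequences)

#' @rdname skimdist-accessors
#' @export
setMethod("taxonLabel", "SkimSeqSet", function(x) x@taxon)

#' @rdname skimdist-accessors
#' @export
setMethod("seqRole", "SkimSeqSet", function(x) x@role)

#' @rdname skimdist-accessors
#' @export
setMethod("totalLength", "SkimSeqSet",
          function(x) sum(Biostrings::width(x@sequences)))

setMethod("show", "SkimSeqSet", function(object) {
  cat("SkimSeqSet '", object@taxon, "' (", object@role, "): ",
      length(object@sequences), " record(s), ",
      totalLength(object), " bp total\n", sep = "")
})

#' Write and read relaxed square PHYLIP distance matrices
#'
#' `writePhylip()` writes the taxon count on the first line, then one
#' row per taxon: the label, whitespace, and the distances with six
#' decimal places.  Undefined entries are written as `NA`.
#' `readPhylip()` reads that dialect back.
#'
#' @param D symmetric numeric matrix with taxon labels as dimnames.
#' @param path file path.
#' @return `writePhylip()` returns `path` invisibly; `readPhylip()`
#'   returns the labelled matrix.
#' @export
writePhylip <- function(D, path) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D),
            !is.null(rownames(D)))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    vals <- ifelse(is.na(D[i, ]), "NA", sprintf("%.6f", D[i, ]))
    writeLines(paste(c(rownames(D)[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writePhylip
#' @export
readPhylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  rows <- strsplit(trimws(lines[1L + seq_len(n)]), "[ \t]+")
  labels <- vapply(rows, `[[`, "", 1L)
  D <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])),
                numeric(n)))
  dimnames(D) <- list(labels, labels)
  D
}
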