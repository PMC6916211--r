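Package: skimdist
Title: Alignment-Free Phylogenetic Distances from Genome Skims via
    Filtered Spaced-Word Matches
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates Jukes-Cantor phylogenetic distances between
    bacterial genomes and/or unassembled sequencing reads without
    alignment or assembly.  Gap-free micro-alignments (spaced-word
    matches with respect to a binary match/don't-care pattern) are
    enumerated between two sequence sets, filtered by their nucleotide
    substitution score at the don't-care positions, and the pooled
    mismatch frequency is corrected for sequencing error and converted
    to a Jukes-Cantor distance.  Includes a fragmented comparison mode
    for assembled genome pairs, all-pairs distance matrices with
    Neighbor-Joining tree reconstruction, and a simulation toolkit
    (genome evolution under the Jukes-Cantor model with indels,
    Illumina-like read sampling) for benchmarking distance recovery at
    sequencing coverages down to 2^-9 X.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
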