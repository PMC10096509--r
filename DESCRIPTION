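Package: trdesign
Title: Silent-Mutation Redesign of Tandem-Repeat Coding Sequences for Assembly PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Redesigns genes encoding protein tandem repeats by exhaustive
    synonymous-codon search so that the repeated DNA regions become mutually
    dissimilar and thermodynamically well behaved, enabling gene construction
    by assembly PCR and site-selective PCR mutagenesis.  Ships a local
    nearest-neighbor two-state hybridization engine (duplex minimum-free-energy
    dynamic programming, two-state melting temperatures, single-strand hairpin
    folding), percentile-based candidate filtering, sequence-identity graph
    clustering, depth-first-search assembly of full-length templates under
    repeat-dissimilarity constraints, and partitioning of the final template
    into a validated alternating-strand oligonucleotide primer set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    GenomicRanges,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
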