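#' Enumerate all synonymous codon combinations of a segment
#'
#' Generates every DNA realization of a peptide segment under the standard
#' genetic code.  Enumeration is lexicographic in the per-residue codon list
#' positions (codon lists are alphabetical, see [geneticCode()]), so the
#' first combination uses the alphabetically first codon of every residue.
#'
#' @param segment one row of a segment data.frame from [segmentRegion()]
#'   (any list with `label`, `start`, `end`, `aa`, optionally `repeatId`).
#' @return A [CodonCombinationSet-class] with
#'   `prod(codonDegeneracy(segment$aa))` combinations.
#' @examples
#' seg <- segmentRegion("MKPVTLY", c(1, 5))[1, ]
#' length(dnaSequences(enumerateSynonymous(seg)))
#' @export
enumerateSynonymous <- function(segment) {
  aa <- .checkPeptide(segment$aa)
  tab <- geneticCode()$table
  deg <- lengths(tab[aa])
  n <- prod(deg)
  # lexicographic index grid: first residue varies slowest
  idx <- vapply(seq_along(aa), function(r) {
    each <- if (r == length(aa)) 1L else prod(deg[(r + 1L):length(aa)])
    rep(rep(seq_len(deg[r]), each = each), length.out = n)
  }, integer(n))
  idx <- matrix(idx, nrow = n)
  codons <- vapply(seq_along(aa), function(r) tab[[aa[r]]][idx[, r]],
                   character(n))
  dna <- apply(matrix(codons, nrow = n), 1L, paste, collapse = "")
  methods::new("CodonCombinationSet",
               label = as.character(segment$label),
               aaSequence = segment$aa,
               residueStart = as.integer(segment$start),
               residueEnd = as.integer(segment$end),
               repeatId = if (is.null(segment$repeatId)) "shared"
                          else as.character(segment$repeatId),
               codonIndices = idx,
               dna = Biostrings::DNAStringSet(dna))
}

#' @rdname CodonCombinationSet-class
#' @export
setMethod("dnaSequences", "CodonCombinationSet",
          function(x) as.character(x@dna))

#' @rdname CodonCombinationSet-class
#' @export
setMethod("codonIndices", "CodonCombinationSet", function(x) x@codonIndices)

#' @rdname CodonCombinationSet-class
#' @export
setMethod("segmentLabel", "CodonCombinationSet", function(x) x@label)

#' @rdname CodonCombinationSet-class
#' @export
setMethod("length", "CodonCombinationSet", function(x) length(x@dna))

#' @rdname CodonCombinationSet-class
#' @param i integer or logical index of combinations to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CodonCombinationSet", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, codonIndices = x@codonIndices[i, , drop = FALSE],
                      dna = x@dna[i])
})

setMethod("show", "CodonCombinationSet", function(object) {
  cat("CodonCombinationSet: segment ", object@label, " (",
      object@repeatId, "), residues ", object@residueStart, "-",
      object@residueEnd, " [", object@aaSequence, "]\n",
      "  ", length(object@dna), " synonymous combination(s)\n", sep = "")
})

#' Combination labels in published list-position style
#'
#' Renders each combination's per-residue codon list positions as a dashed
#' label (e.g. "1-1-1-1-6").
#'
#' @param x a [CodonCombinationSet-class].
#' @return character vector of labels.
#' @export
combinationLabels <- function(x) {
  apply(codonIndices(x), 1L, paste, collapse = "-")
}

#' Write codon combinations to a TSV dump
#'
#' @param x a [CodonCombinationSet-class].
#' @param path output file.
#' @export
writeCombinations <- function(x, path) {
  write.table(data.frame(segment = segmentLabel(x),
                         label = combinationLabels(x),
                         dna = dnaSequences(x)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
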