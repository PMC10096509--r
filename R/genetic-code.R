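#' The standard genetic code as an ordered codon table
#'
#' Returns the standard genetic code organized for synonymous-codon
#' enumeration: for every amino-acid letter, the alphabetically ordered list
#' of its codons.  The alphabetical order is the stable "list position" used
#' to label codon combinations, so combination labels are reproducible
#' across runs and machines.
#'
#' @return A list with components `table` (named list, amino-acid letter ->
#'   character vector of codons, alphabetical) and `degeneracy` (named
#'   integer vector of codon counts).
#' @examples
#' code <- geneticCode()
#' code$degeneracy[c("M", "W", "L")] # 1, 1, 6
#' @export
geneticCode <- function() {
  if (!is.null(.trdesign_cache$code)) return(.trdesign_cache$code)
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  tab <- split(names(sense), unname(sense))
  tab <- lapply(tab, sort)
  code <- list(table = tab,
               degeneracy = vapply(tab, length, integer(1)))
  .trdesign_cache$code <- code
  code
}

#' Per-residue codon degeneracy of a peptide
#'
#' @param peptide amino-acid string (standard 20-letter alphabet).
#' @return Integer vector of codon counts, one per residue.
#' @examples
#' codonDegeneracy("KPVTL") # 2 4 4 4 6
#' @export
codonDegeneracy <- function(peptide) {
  aa <- .checkPeptide(peptide)
  unname(geneticCode()$degeneracy[aa])
}

.checkPeptide <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1)
  aa <- strsplit(toupper(peptide), "")[[1]]
  bad <- setdiff(aa, names(geneticCode()$degeneracy))
  if (length(bad))
    stop("non-standard amino-acid letter(s): ", paste(unique(bad),
         collapse = ", "), call. = FALSE)
  aa
}

.checkDna <- function(dna, what = "dna") {
  stopifnot(is.character(dna), length(dna) == 1)
  dna <- toupper(dna)
  if (nchar(dna) == 0 || grepl("[^ACGT]", dna))
    stop(what, " must be a non-empty A/C/G/T string", call. = FALSE)
  dna
}

#' Reverse complement of a DNA string
#'
#' Strict A/C/G/T reverse complement (ambiguity codes are rejected rather
#' than propagated, since every downstream thermodynamic metric assumes an
#' unambiguous strand).
#'
#' @param dna nucleotide string (A/C/G/T only).
#' @return The reverse complement, 5'->3'.
#' @examples
#' revComp("GATC") # palindromic
#' @export
revComp <- function(dna) {
  dna <- .checkDna(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Translate an in-frame coding sequence
#'
#' @param dna nucleotide string, length a multiple of 3.
#' @return Amino-acid string (stop codons rendered as `*`).
#' @export
translateDNA <- function(dna) {
  dna <- .checkDna(dna)
  if (nchar(dna) %% 3 != 0)
    stop("dna length must be a multiple of 3", call. = FALSE)
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Back-translate a peptide using first-listed codons
#'
#' Deterministic back-translation taking the alphabetically first codon of
#' every residue; used to fabricate "wild-type" coding sequences for
#' synthetic fixtures.
#'
#' @inheritParams codonDegeneracy
#' @return Nucleotide string of length `3 * nchar(peptide)`.
#' @export
backTranslate <- function(peptide) {
  aa <- .checkPeptide(peptide)
  tab <- geneticCode()$table
  paste(vapply(aa, function(a) tab[[a]][1], character(1)), collapse = "")
}
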