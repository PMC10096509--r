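# Bundled design fixtures and the synthetic tandem-repeat generator.

#' The single-chain LacI DNA-binding-domain design fixture
#'
#' Loads the bundled fixture for the published single-chain tandem-repeat
#' LacI DNA-binding-domain repressor (scDBD): the 89-residue domain peptide
#' (DFT operator-specificity variant), the per-segment dissection of the
#' two redesigned regions (residues 1-29, segments A-E; residues 60-89,
#' segments F-K; the segment boundary table is a synthetic reconstruction,
#' see its file header), and the published assembly/flanking primer table
#' with its printed thermodynamic predictions.
#'
#' @return list with `protein` (89-aa domain peptide), `segments`
#'   (label/start/end/aa data.frame), `primers` (primer table incl.
#'   printed `t_ff`, `t_rr`, `t_fr`, `dg_f72`, `dg_r72` columns),
#'   `regions` (residue ranges of the two redesigned regions).
#' @export
dbdFixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "trdesign",
                                 mustWork = TRUE)
  protein <- readProteinFasta(ext("dbd_peptide.fasta"))
  segments <- readSegmentTable(ext("dbd_segments_synthetic.tsv"))
  aa <- strsplit(protein, "")[[1]]
  segments$aa <- vapply(seq_len(nrow(segments)), function(i)
    paste(aa[segments$start[i]:segments$end[i]], collapse = ""),
    character(1))
  segments$repeatId <- "shared"
  primers <- read.delim(ext("dbd_primers.tsv"), comment.char = "#",
                        stringsAsFactors = FALSE)
  list(protein = protein, segments = segments, primers = primers,
       regions = list(N = c(1L, 29L), C = c(60L, 89L)))
}

#' Ordered primers of one assembly-PCR fragment
#'
#' Selects, in assembly order with alternating strands (starting forward),
#' the primers of one of the four fragments of the scDBD synthesis: `N1`
#' (repeat copy 1, residues 1-29), `N2` (copy 1, residues 60-89), `C1`
#' (copy 2, residues 1-29), `C2` (copy 2, residues 60-89).
#'
#' @param fixture result of [dbdFixture()].
#' @param fragment one of "N1", "N2", "C1", "C2".
#' @param variant which operator-specificity variant's mutation-carrying
#'   primers to use ("DFT" or "IAN").
#' @return data.frame with columns `name`, `dna`, `strand`.
#' @export
fragmentPrimers <- function(fixture, fragment, variant = "DFT") {
  p <- fixture$primers
  sel <- p[!is.na(p$fragment) & p$fragment == fragment &
             p$variant %in% c("common", variant), , drop = FALSE]
  # restore assembly order (file order is assembly order per fragment)
  data.frame(name = sel$name, dna = sel$sequence,
             strand = rep(c("forward", "reverse"),
                          length.out = nrow(sel)),
             stringsAsFactors = FALSE)
}

#' Locate a peptide's coding region inside an assembled fragment
#'
#' Scans the three forward reading frames for an exact translation match
#' and returns the matching coding DNA.
#'
#' @param template nucleotide string.
#' @param peptide amino-acid string to locate.
#' @return the in-frame coding subsequence (length `3 * nchar(peptide)`).
#' @export
locateCodingRegion <- function(template, peptide) {
  template <- .checkDna(template, "template")
  for (f in 0:2) {
    sub <- substr(template, f + 1L,
                  f + 3L * ((nchar(template) - f) %/% 3L))
    tr <- translateDNA(sub)
    hit <- regexpr(peptide, tr, fixed = TRUE)
    if (hit > 0) {
      s <- f + 3L * (as.integer(hit) - 1L) + 1L
      return(substr(template, s, s + 3L * nchar(peptide) - 1L))
    }
  }
  stop("peptide not found in any forward reading frame", call. = FALSE)
}

#' Reconstruct the redesigned repeat regions from the published primers
#'
#' Overlap-assembles the four scDBD fragments from the bundled primer
#' table ([assemblePrimers()]), locates the redesigned coding regions
#' (residues 1-29 and 60-89 of each repeat copy) by translation, and
#' reports the codon-aligned percent identity between the two copies over
#' the 59 redesigned codons.
#'
#' @param fixture result of [dbdFixture()].
#' @param variant "DFT" (default) or "IAN".
#' @return list with `dbdN`, `dbdC` (177-nt redesigned coding sequences),
#'   `identity` (percent), `nCodons`.
#' @export
redesignedRegions <- function(fixture = dbdFixture(), variant = "DFT") {
  pepN <- substr(fixture$protein, fixture$regions$N[1],
                 fixture$regions$N[2])
  pepC <- substr(fixture$protein, fixture$regions$C[1],
                 fixture$regions$C[2])
  if (variant == "IAN") {
    # IAN operator-specificity triple mutation at residues 17/18/22
    v <- strsplit(pepN, "")[[1]]
    v[17] <- "I"; v[18] <- "A"; v[22] <- "N"
    pepN <- paste(v, collapse = "")
  }
  asm <- function(frag) {
    pr <- fragmentPrimers(fixture, frag, variant)
    assemblePrimers(pr$dna, pr$strand)
  }
  dbdN <- paste0(locateCodingRegion(asm("N1"), pepN),
                 locateCodingRegion(asm("N2"), pepC))
  dbdC <- paste0(locateCodingRegion(asm("C1"), pepN),
                 locateCodingRegion(asm("C2"), pepC))
  list(dbdN = dbdN, dbdC = dbdC,
       identity = percentIdentity(dbdN, dbdC),
       nCodons = nchar(dbdN) %/% 3L)
}

#' Generate a synthetic tandem-repeat design fixture
#'
#' Draws a random peptide (rejecting draws where more than half the
#' residues are the non-degenerate Met/Trp, which would collapse the codon
#' space), duplicates it `nRepeats` times, and back-translates a synthetic
#' "wild-type" coding sequence using first-listed codons — the worst case
#' of 100% repeat-vs-repeat DNA identity that the redesign must break.
#'
#' @param peptideLen repeat-unit length in residues (5-30).
#' @param nRepeats number of tandem copies (>= 2).
#' @param seed integer seed; the fixture is reproducible.
#' @return list with `name`, `protein` (repeat unit), `nRepeats`,
#'   `fullProtein`, `wtCds` (unit coding sequence), `fullWtCds`.
#' @export
generateToyTR <- function(peptideLen = 10L, nRepeats = 2L, seed = 1L) {
  stopifnot(peptideLen >= 5, peptideLen <= 30, nRepeats >= 2)
  aas <- names(geneticCode()$degeneracy)
  unit <- withr::with_seed(seed, {
    repeat {
      p <- paste(sample(aas, peptideLen, replace = TRUE), collapse = "")
      mw <- sum(strsplit(p, "")[[1]] %in% c("M", "W"))
      if (mw <= peptideLen / 2) break
    }
    p
  })
  wt <- backTranslate(unit)
  list(name = sprintf("toyTR_L%d_x%d_s%d", peptideLen, nRepeats, seed),
       protein = unit, nRepeats = as.integer(nRepeats),
       fullProtein = strrep(unit, nRepeats),
       wtCds = wt, fullWtCds = strrep(wt, nRepeats))
}
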