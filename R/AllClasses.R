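#' Nearest-neighbor DNA hybridization parameter set
#'
#' Holds the unified nearest-neighbor stack enthalpies/entropies, duplex
#' initiation terms, loop penalty schedules, and the reaction conditions
#' (monovalent salt, total strand concentration) used by the two-state
#' hybridization engine.  Construct with [nnParameters()].
#'
#' @slot stackDH,stackDS named numeric(16): stack enthalpy (kcal/mol) and
#'   entropy (cal/mol/K) indexed by the top-strand dinucleotide 5'->3', the
#'   bottom strand being its Watson-Crick complement.
#' @slot initDH,initDS named numeric(2) (`AT`, `GC`): per-end duplex
#'   initiation terms applied according to the terminal base pair.
#' @slot symmetryDS numeric(1): entropic symmetry correction (cal/mol/K)
#'   added for self-complementary duplexes.
#' @slot hairpinLoopDG37,bulgeLoopDG37,internalLoopDG37 numeric vectors of
#'   loop free energies at 37 degC (kcal/mol) indexed by loop size 1..n;
#'   larger loops are extrapolated logarithmically.
#' @slot sodium monovalent cation concentration (mol/L).
#' @slot ct total strand concentration \eqn{C_T} (mol/L).
#' @slot maxLoop integer: largest bulge/internal-loop extent explored per
#'   strand by the duplex dynamic program.
#' @slot tmOffset additive calibration offset (degC) applied to every
#'   reported melting temperature; see [calibrateTmOffset()].
#'
#' @seealso [hybridizationTm()], [duplexMFE()], [foldDG()]
#' @exportClass NNParameters
setClass("NNParameters", representation(
  stackDH = "numeric", stackDS = "numeric",
  initDH = "numeric", initDS = "numeric",
  symmetryDS = "numeric",
  hairpinLoopDG37 = "numeric", bulgeLoopDG37 = "numeric",
  internalLoopDG37 = "numeric",
  sodium = "numeric", ct = "numeric",
  maxLoop = "integer", tmOffset = "numeric"))

setValidity("NNParameters", function(object) {
  msgs <- character()
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  if (!all(dinucs %in% names(object@stackDH)) ||
      !all(dinucs %in% names(object@stackDS)))
    msgs <- c(msgs, "stackDH/stackDS must cover all 16 ACGT dinucleotides")
  if (!all(c("AT", "GC") %in% names(object@initDH)) ||
      !all(c("AT", "GC") %in% names(object@initDS)))
    msgs <- c(msgs, "initDH/initDS must have entries 'AT' and 'GC'")
  if (length(object@ct) != 1 || object@ct <= 0)
    msgs <- c(msgs, "ct must be a single positive strand concentration")
  if (length(object@sodium) != 1 || object@sodium <= 0)
    msgs <- c(msgs, "sodium must be a single positive molarity")
  if (length(msgs)) msgs else TRUE
})

#' Synonymous codon combinations of one peptide segment
#'
#' The exhaustive set of DNA realizations of a peptide segment under a
#' genetic code, labeled by per-residue codon list positions.  Construct
#' with [enumerateSynonymous()].
#'
#' @slot label segment label (single letter, "A", "B", ...).
#' @slot aaSequence amino-acid sequence of the segment (5-7 residues).
#' @slot residueStart,residueEnd 1-based inclusive residue range on the
#'   target protein.
#' @slot repeatId which repeat copy the segment belongs to ("shared" when
#'   the same peptide is reused by all copies).
#' @slot codonIndices integer matrix (combinations x residues): position of
#'   the chosen codon in the alphabetically ordered codon list per residue.
#' @slot dna [Biostrings::DNAStringSet] of the combination sequences, one
#'   per row of `codonIndices`.
#'
#' @exportClass CodonCombinationSet
setClass("CodonCombinationSet", representation(
  label = "character", aaSequence = "character",
  residueStart = "integer", residueEnd = "integer",
  repeatId = "character",
  codonIndices = "matrix", dna = "DNAStringSet"))

setValidity("CodonCombinationSet", function(object) {
  msgs <- character()
  nres <- nchar(object@aaSequence)
  if (ncol(object@codonIndices) != nres)
    msgs <- c(msgs, "codonIndices must have one column per residue")
  if (length(object@dna) != nrow(object@codonIndices))
    msgs <- c(msgs, "dna and codonIndices must have matching rows")
  if (length(object@dna) &&
      !all(Biostrings::width(object@dna) == 3L * nres))
    msgs <- c(msgs, "every DNA entry must be 3x the peptide length")
  if (object@residueEnd - object@residueStart + 1L != nres)
    msgs <- c(msgs, "residue range does not match the peptide length")
  if (length(msgs)) msgs else TRUE
})

#' A rendered tandem-repeat design template
#'
#' The full-length redesigned coding sequence produced from one design path,
#' with per-codon provenance annotations and a repeat-identity report.
#' Construct with [renderTemplate()].
#'
#' @slot dna [Biostrings::DNAString] coding sequence.
#' @slot protein the protein the template must translate to.
#' @slot annotations data.frame with one row per annotated codon run:
#'   columns `segment`, `repeatId`, `group`, `combination`, `resStart`,
#'   `resEnd`, `ntStart`, `ntEnd`, `source` ("design" or "fixed").
#' @slot identityReport list of percent identities (repeat vs repeat over
#'   the redesigned codons; each repeat vs wild-type when available).
#'
#' @exportClass DesignTemplate
setClass("DesignTemplate", representation(
  dna = "DNAString", protein = "character",
  annotations = "data.frame", identityReport = "list"))

setValidity("DesignTemplate", function(object) {
  msgs <- character()
  if (length(object@dna) != 3L * nchar(object@protein))
    msgs <- c(msgs, "template length must be 3x the protein length")
  ann <- object@annotations
  need <- c("segment", "repeatId", "group", "combination",
            "resStart", "resEnd", "ntStart", "ntEnd", "source")
  if (!all(need %in% names(ann)))
    msgs <- c(msgs, "annotations are missing required columns")
  else {
    ord <- ann[order(ann$ntStart), , drop = FALSE]
    if (nrow(ord) == 0 || ord$ntStart[1] != 1L ||
        ord$ntEnd[nrow(ord)] != length(object@dna) ||
        (nrow(ord) > 1 &&
         !all(ord$ntStart[-1] == ord$ntEnd[-nrow(ord)] + 1L)))
      msgs <- c(msgs, "annotations must tile the template exactly")
  }
  if (length(msgs)) msgs else TRUE
})

#' An alternating-strand assembly-PCR primer set
#'
#' Primers tiling a design template on alternating strands, with per-primer
#' thermodynamics, per-junction overlap melting temperatures, and an
#' all-vs-all cross-hybridization matrix.  Construct with
#' [partitionPrimers()].
#'
#' @slot primers data.frame: `name`, `strand` ("forward"/"reverse"), `dna`
#'   (5'->3' of its own strand), `start`, `end` (template coordinates),
#'   `t_ff`, `t_rr`, `t_fr` (degC) and `dg_fold_72` (kcal/mol).
#' @slot overlaps data.frame of consecutive-primer overlaps: `left`,
#'   `right`, `start`, `end`, `sequence`, `tm`.
#' @slot crossMatrix symmetric numeric matrix of pairwise hybridization Tm
#'   (degC) between primers as given (diagonal: self-dimer Tm).
#' @slot template character: the tiled template sequence.
#'
#' @exportClass PrimerSet
setClass("PrimerSet", representation(
  primers = "data.frame", overlaps = "data.frame",
  crossMatrix = "matrix", template = "character"))

setValidity("PrimerSet", function(object) {
  msgs <- character()
  p <- object@primers
  need <- c("name", "strand", "dna", "start", "end")
  if (!all(need %in% names(p)))
    msgs <- c(msgs, "primers must have name/strand/dna/start/end columns")
  else {
    if (!all(p$strand %in% c("forward", "reverse")))
      msgs <- c(msgs, "strand must be 'forward' or 'reverse'")
    if (nrow(p) && (p$start[1] != 1L ||
                    p$end[nrow(p)] != nchar(object@template)))
      msgs <- c(msgs, "primer spans must cover the template")
    if (nrow(p) > 1 && !all(p$start[-1] <= p$end[-nrow(p)]))
      msgs <- c(msgs, "consecutive primers must overlap")
  }
  if (nrow(object@crossMatrix) &&
      nrow(object@crossMatrix) != nrow(p))
    msgs <- c(msgs, "crossMatrix dimension must match the primer count")
  if (length(msgs)) msgs else TRUE
})
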