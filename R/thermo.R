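# Two-state nearest-neighbor hybridization engine.
#
# All temperatures are Kelvin internally and Celsius at every interface.
# When no duplex (or no melting transition) exists, Tm is reported as the
# sentinel -273.15 degC with a flag, so percentile filters stay monotone.

.TM_SENTINEL <- -273.15
.RGAS <- 1.9872  # cal / (mol K)

#' Minimum-free-energy intermolecular duplex
#'
#' Finds the optimal antiparallel intermolecular pairing between two strands
#' at a given temperature by dynamic programming over Watson-Crick
#' nearest-neighbor stacks with bulge and internal-loop penalties (no
#' intramolecular pairs, no multiloops), and returns the accumulated
#' enthalpy/entropy of that structure.
#'
#' @param seqA,seqB nucleotide strings, 5'->3', A/C/G/T, length 2-60.
#' @param params an [NNParameters-class] object.
#' @param temp evaluation temperature in degC (default 37).
#' @return list with `found` (any Watson-Crick pairing at all), `dH`
#'   (kcal/mol), `dS` (cal/mol/K), `dGatT` (kcal/mol at `temp`), `tm`
#'   (degC, uncalibrated, two-state at `params@ct`), `selfComplementary`,
#'   `npairs` and `pairing` (two-column matrix of paired positions).
#' @export
duplexMFE <- function(seqA, seqB, params = nnParameters(), temp = 37) {
  seqA <- .checkDna(seqA, "seqA"); seqB <- .checkDna(seqB, "seqB")
  if (nchar(seqA) > 60 || nchar(seqB) > 60)
    stop("duplex sequences are limited to 60 nt", call. = FALSE)
  st <- .stackVectors(params); ini <- .initVectors(params)
  res <- duplex_mfe_cpp(.encodeDna(seqA), .encodeDna(seqB),
                        st$dH, st$dS,
                        params@bulgeLoopDG37, params@internalLoopDG37,
                        ini$dH, ini$dS,
                        temp + 273.15, params@maxLoop)
  selfComp <- identical(seqA, seqB)
  if (!res$found)
    return(list(found = FALSE, dH = NA_real_, dS = NA_real_,
                dGatT = NA_real_, tm = .TM_SENTINEL,
                selfComplementary = selfComp, npairs = 0L,
                pairing = res$pairs))
  dH <- res$dH
  dS <- res$dS
  # the symmetry entropy enters the melting bookkeeping only, not the
  # reported structure thermodynamics
  tm <- .twoStateTmC(dH, dS + if (selfComp) params@symmetryDS else 0,
                     params@ct, selfComp, params, npairs = res$npairs)
  list(found = TRUE, dH = dH, dS = dS,
       dGatT = dH - (temp + 273.15) * dS / 1000,
       tm = tm, selfComplementary = selfComp,
       npairs = res$npairs, pairing = res$pairs)
}

# uncalibrated two-state Tm in degC (sentinel when no transition)
.twoStateTmC <- function(dH, dS, ct, selfComp, params, npairs = NULL) {
  f <- if (selfComp) 1 else 4
  if (!is.null(npairs) && npairs > 1 && params@sodium != 1)
    dS <- dS + 0.368 * (npairs - 1) * log(params@sodium)
  den <- dS + .RGAS * log(ct / f)
  if (!is.finite(dH) || dH >= 0 || den >= 0) return(.TM_SENTINEL)
  1000 * dH / den - 273.15
}

#' Two-state melting temperature from duplex enthalpy and entropy
#'
#' \eqn{T_m = 1000 \Delta H / (\Delta S + R \ln(C_T / f))} with f = 1 for
#' self-complementary duplexes and f = 4 otherwise, salt-corrected per the
#' parameter set and converted to degC.  Degenerate inputs (non-negative
#' enthalpy, or a non-negative denominator) have no melting transition and
#' return the sentinel -273.15 with attribute `flag = "no transition"`.
#'
#' @param dH duplex enthalpy, kcal/mol.
#' @param dS duplex entropy, cal/mol/K.
#' @param ct total strand concentration, mol/L (defaults to the parameter
#'   set's).
#' @param selfComplementary logical.
#' @param params an [NNParameters-class] object.
#' @param npairs number of base pairs (used by the salt correction).
#' @return Tm in degC (uncalibrated; no `tmOffset` applied).
#' @export
twoStateTm <- function(dH, dS, ct = NULL, selfComplementary = FALSE,
                       params = nnParameters(), npairs = NULL) {
  ct <- ct %||% params@ct
  tm <- .twoStateTmC(dH, dS, ct, selfComplementary, params, npairs)
  if (tm == .TM_SENTINEL) attr(tm, "flag") <- "no transition"
  tm
}

#' Hybridization melting temperature of two strands
#'
#' Composition of [duplexMFE()] and the two-state Tm: the optimal duplex is
#' found at 37 degC and its enthalpy/entropy converted to a melting
#' temperature at the parameter set's strand concentration.  A homodimer
#' call (`seqB` identical to `seqA`, which includes a self-complementary
#' sequence against its own reverse complement) uses f = 1 plus the
#' symmetry correction.  The calibration offset `params@tmOffset` is added
#' to every finite result.
#'
#' @inheritParams duplexMFE
#' @return Tm in degC; sentinel -273.15 (flagged) when no duplex forms.
#' @export
hybridizationTm <- function(seqA, seqB, params = nnParameters()) {
  res <- duplexMFE(seqA, seqB, params)
  if (!res$found || res$tm == .TM_SENTINEL) {
    tm <- .TM_SENTINEL
    attr(tm, "flag") <- if (!res$found) "no stable duplex" else
      "no melting transition"
    return(tm)
  }
  res$tm + params@tmOffset
}

#' Single-strand hairpin folding free energy
#'
#' Minimum folding free energy of the best hairpin (stem of Watson-Crick
#' stacks with bulges/internal loops closed by a loop of >= 3 nt) at the
#' given temperature; loop penalties are treated as purely entropic.  When
#' no hairpin can form at all the strand is flagged linear and the unfolded
#' reference 0.0 is returned.
#'
#' @param seq nucleotide string (<= 60 nt).
#' @param temp temperature in degC.
#' @param params an [NNParameters-class] object.
#' @return dG in kcal/mol with attribute `linear` (TRUE when no hairpin is
#'   geometrically possible).
#' @export
foldDG <- function(seq, temp = 72, params = nnParameters()) {
  seq <- .checkDna(seq, "seq")
  if (nchar(seq) > 60) stop("sequence limited to 60 nt", call. = FALSE)
  st <- .stackVectors(params)
  res <- hairpin_mfe_cpp(.encodeDna(seq), st$dH, st$dS,
                         params@hairpinLoopDG37, params@bulgeLoopDG37,
                         params@internalLoopDG37,
                         temp + 273.15, params@maxLoop, 3L)
  dg <- res$dG
  attr(dg, "linear") <- !res$found
  dg
}

#' Four-temperature thermodynamic profile of candidate sequences
#'
#' For each forward sequence F computes the self-dimer melting temperatures
#' \eqn{T_{FF}} (F vs F) and \eqn{T_{RR}} (R vs R, R = reverse complement
#' of F), the intended-duplex \eqn{T_{FR}} (F vs R) and, when a wild-type
#' window is supplied, \eqn{T_{WT}} (F vs the reverse complement of the
#' wild-type sequence spanning the same residues).
#'
#' @param dna character vector of forward sequences (e.g.
#'   `dnaSequences(combos)`).
#' @param wtWindow wild-type DNA spanning the same region, or `NULL`.
#' @param params an [NNParameters-class] object.
#' @return data.frame with columns `t_ff`, `t_rr`, `t_fr` and (when
#'   `wtWindow` is given) `t_wt`, in degC.
#' @export
thermoProfile <- function(dna, wtWindow = NULL, params = nnParameters()) {
  wt_rc <- if (!is.null(wtWindow)) revComp(wtWindow)
  prof <- t(vapply(dna, function(f) {
    r <- revComp(f)
    c(t_ff = as.numeric(hybridizationTm(f, f, params)),
      t_rr = as.numeric(hybridizationTm(r, r, params)),
      t_fr = as.numeric(hybridizationTm(f, r, params)),
      t_wt = if (is.null(wt_rc)) NA_real_ else
        as.numeric(hybridizationTm(f, wt_rc, params)))
  }, numeric(4)))
  prof <- as.data.frame(prof, row.names = seq_along(dna))
  if (is.null(wtWindow)) prof$t_wt <- NULL
  prof
}

#' Calibrate the engine's Tm offset against a reference primer table
#'
#' Published two-state melting predictions depend on unstated buffer and
#' parameter choices; a single additive offset (the least-absolute-error
#' constant, i.e. the median residual) is fitted so the engine's
#' perfect-duplex \eqn{T_{FR}} matches a set of reference primers, and is
#' then applied to every reported Tm.  The fit is a transparent, reported
#' constant, not a per-sequence adjustment.
#'
#' @param sequences character vector of primer sequences.
#' @param referenceTm numeric vector of reference \eqn{T_{FR}} values
#'   (degC).
#' @param params an [NNParameters-class] object to calibrate.
#' @return `params` with `tmOffset` set; the fitted offset and residuals
#'   are attached as attributes `offset` and `residuals`.
#' @export
calibrateTmOffset <- function(sequences, referenceTm,
                              params = nnParameters()) {
  stopifnot(length(sequences) == length(referenceTm),
            length(sequences) > 0)
  base <- params
  base@tmOffset <- 0
  model <- vapply(sequences, function(s)
    as.numeric(hybridizationTm(s, revComp(s), base)), numeric(1))
  off <- stats::median(referenceTm - model)
  out <- params
  out@tmOffset <- off
  attr(out, "offset") <- off
  attr(out, "residuals") <- referenceTm - (model + off)
  out
}
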