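# Adjacent-segment joining, pair filtering, depth-first path search and
# template rendering.

#' Join adjacent-segment codon combinations
#'
#' Forms the Cartesian product of two consecutive segments' surviving
#' combinations, concatenates each pair and computes the joined sequence's
#' self-dimer and perfect-duplex melting temperatures.
#'
#' @param leftDna,rightDna character vectors of surviving combination
#'   sequences for two consecutive segments.
#' @param params an [NNParameters-class] object.
#' @return data.frame with columns `left`, `right` (indices into the input
#'   vectors), `dna`, `t_ff`, `t_rr`, `t_fr`.
#' @export
joinAdjacent <- function(leftDna, rightDna, params = nnParameters()) {
  if (!length(leftDna) || !length(rightDna))
    stop("segment exhausted: empty survivor list", call. = FALSE)
  grid <- expand.grid(left = seq_along(leftDna),
                      right = seq_along(rightDna))
  grid$dna <- paste0(leftDna[grid$left], rightDna[grid$right])
  prof <- thermoProfile(grid$dna, params = params)
  cbind(grid, prof)
}

#' Thermodynamic filtering of joined adjacent pairs
#'
#' Discards joined pairs whose self-dimer melting temperature (`t_ff` or
#' `t_rr`) lies in the top `qHomo` of that metric's distribution for this
#' junction, and keeps only pairs whose perfect-duplex `t_fr` reaches the
#' fixed floor `tFrMin`.
#'
#' @param pairs data.frame from [joinAdjacent()].
#' @param qHomo top fraction of the homodimer distributions to discard
#'   (default 0.20).
#' @param tFrMin fixed heterodimer floor in degC (default 80).
#' @param junction optional junction label for error messages.
#' @return the surviving rows, with attributes `cutoffs` and
#'   `reductionFraction`.
#' @export
filterPairs <- function(pairs, qHomo = 0.20, tFrMin = 80.0,
                        junction = "?") {
  cut_ff <- percentileThreshold(pairs$t_ff, 1 - qHomo)
  cut_rr <- percentileThreshold(pairs$t_rr, 1 - qHomo)
  keep <- pairs$t_ff <= cut_ff & pairs$t_rr <= cut_rr &
    pairs$t_fr >= tFrMin
  if (!any(keep))
    stop("junction ", junction, " exhausted: no adjacent pair passes ",
         "the thresholds", call. = FALSE)
  structure(pairs[keep, , drop = FALSE],
            cutoffs = c(t_ff = cut_ff, t_rr = cut_rr, t_fr = tFrMin),
            reductionFraction = 1 - mean(keep))
}

#' Depth-first search for full-length design paths
#'
#' Searches for up to `nPaths` assignments of one codon combination per
#' (repeat copy, segment) slot such that (i) every constrained junction
#' between consecutive segments within a repeat copy uses a surviving
#' adjacent pair and (ii) for every segment, the combinations chosen for
#' different repeat copies belong to different similarity groups — the
#' constraint that makes the repeat copies mutually dissimilar.  Candidates
#' are visited in descending `t_fr` order with seed-shuffled ties, so the
#' search is reproducible and favors strongly assembling sequences.
#'
#' @param candidates named list (by segment label) of data.frames with
#'   columns `dna`, `group`, `t_fr` — the post-sampling survivors.
#' @param segmentOrder character vector of segment labels in template
#'   order for one repeat copy.
#' @param allowedPairs named list (by junction label `"A+B"`) of
#'   two-column matrices of allowed (left, right) candidate indices;
#'   junctions absent from the list are unconstrained.
#' @param copies number of repeat copies (default 2).
#' @param nPaths maximum number of paths to return (default 100).
#' @param seed integer seed for tie shuffling.
#' @return list of paths; each path is a data.frame with columns `copy`,
#'   `segment`, `idx`, `group`, `dna` ordered copy-major.
#' @export
dfsPaths <- function(candidates, segmentOrder, allowedPairs = list(),
                     copies = 2L, nPaths = 100L, seed = 1L) {
  stopifnot(all(segmentOrder %in% names(candidates)), copies >= 1)
  nseg <- length(segmentOrder)
  slots <- data.frame(
    copy = rep(seq_len(copies), each = nseg),
    segment = rep(segmentOrder, copies),
    stringsAsFactors = FALSE)
  nslot <- nrow(slots)
  # allowed-pair lookup as logical matrices per junction
  pairOK <- lapply(allowedPairs, function(m) {
    m <- as.matrix(m)[, 1:2, drop = FALSE]
    m
  })
  pairSet <- lapply(pairOK, function(m) paste(m[, 1], m[, 2]))
  # candidate visiting order per segment: descending t_fr, seeded ties
  orders <- withr::with_seed(seed, lapply(segmentOrder, function(lab) {
    cand <- candidates[[lab]]
    order(-cand$t_fr, sample.int(nrow(cand)))
  }))
  names(orders) <- segmentOrder

  paths <- list()
  choice <- integer(nslot)
  deepest <- 0L
  dfs <- function(slot) {
    if (length(paths) >= nPaths) return()
    if (slot > nslot) {
      rows <- lapply(seq_len(nslot), function(s) {
        cand <- candidates[[slots$segment[s]]]
        data.frame(copy = slots$copy[s], segment = slots$segment[s],
                   idx = choice[s], group = cand$group[choice[s]],
                   dna = cand$dna[choice[s]], stringsAsFactors = FALSE)
      })
      paths[[length(paths) + 1L]] <<- do.call(rbind, rows)
      return()
    }
    lab <- slots$segment[slot]
    cand <- candidates[[lab]]
    segpos <- match(lab, segmentOrder)
    junction <- if (segpos > 1)
      paste0(segmentOrder[segpos - 1L], "+", lab)
    for (i in orders[[lab]]) {
      # junction constraint within the current repeat copy
      if (!is.null(junction) && !is.null(pairSet[[junction]])) {
        prev <- choice[slot - 1L]
        if (!(paste(prev, i) %in% pairSet[[junction]])) next
      }
      # group distinctness across repeat copies of the same segment
      ok <- TRUE
      if (slots$copy[slot] > 1L) {
        for (c0 in seq_len(slots$copy[slot] - 1L)) {
          s0 <- (c0 - 1L) * nseg + segpos
          if (cand$group[choice[s0]] == cand$group[i]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      choice[slot] <<- i
      if (slot > deepest) deepest <<- slot
      dfs(slot + 1L)
      if (length(paths) >= nPaths) return()
    }
  }
  dfs(1L)
  if (!length(paths)) {
    blk <- min(deepest + 1L, nslot)
    stop("design infeasible: no valid path; first blocking slot is ",
         "segment ", slots$segment[blk], " of repeat copy ",
         slots$copy[blk], call. = FALSE)
  }
  paths
}

#' Render a design path into a full-length template
#'
#' Splices the chosen codon combinations of every repeat copy around the
#' fixed (unchanged) regions into the final coding sequence, enforces the
#' translation check, and computes the repeat-identity report.
#'
#' @param path one element of [dfsPaths()]'s result.
#' @param protein amino-acid sequence of one repeat unit.
#' @param segments segment data.frame from [segmentRegion()] (labels must
#'   match the path).
#' @param fixedRegions optional data.frame with columns `start`, `end`,
#'   `dna`: wild-type DNA for every residue range not covered by segments.
#' @param wtCds optional wild-type coding sequence of one repeat unit,
#'   used for the identity-vs-wild-type report.
#' @return A [DesignTemplate-class]; its protein is `protein` repeated
#'   once per copy.
#' @export
renderTemplate <- function(path, protein, segments, fixedRegions = NULL,
                           wtCds = NULL) {
  aa <- .checkPeptide(protein)
  copies <- sort(unique(path$copy))
  nres <- length(aa)
  covered <- rep(FALSE, nres)
  for (i in seq_len(nrow(segments)))
    covered[segments$start[i]:segments$end[i]] <- TRUE
  if (!is.null(fixedRegions))
    for (i in seq_len(nrow(fixedRegions)))
      covered[fixedRegions$start[i]:fixedRegions$end[i]] <- TRUE
  if (!all(covered))
    stop("coverage gap: residues ",
         paste(which(!covered), collapse = ","),
         " are neither segmented nor fixed", call. = FALSE)

  pieces <- character(0)
  ann <- list()
  ntpos <- 0L
  segDna <- list()
  for (cp in copies) {
    sub <- path[path$copy == cp, , drop = FALSE]
    # order blocks by residue start
    blocks <- rbind(
      data.frame(start = segments$start, end = segments$end,
                 segment = segments$label, source = "design",
                 stringsAsFactors = FALSE),
      if (!is.null(fixedRegions))
        data.frame(start = fixedRegions$start, end = fixedRegions$end,
                   segment = NA_character_, source = "fixed",
                   stringsAsFactors = FALSE))
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    for (b in seq_len(nrow(blocks))) {
      if (blocks$source[b] == "design") {
        row <- sub[sub$segment == blocks$segment[b], , drop = FALSE]
        if (nrow(row) != 1)
          stop("path does not choose exactly one combination for segment ",
               blocks$segment[b], call. = FALSE)
        dna <- row$dna
        grp <- row$group
        combo <- row$idx
        segDna[[as.character(cp)]] <-
          paste0(segDna[[as.character(cp)]] %||% "", dna)
      } else {
        dna <- fixedRegions$dna[fixedRegions$start == blocks$start[b]]
        grp <- NA_integer_
        combo <- NA_integer_
      }
      ann[[length(ann) + 1L]] <- data.frame(
        segment = blocks$segment[b], repeatId = paste0("copy", cp),
        group = grp, combination = combo,
        resStart = blocks$start[b], resEnd = blocks$end[b],
        ntStart = ntpos + 1L, ntEnd = ntpos + nchar(dna),
        source = blocks$source[b], stringsAsFactors = FALSE)
      ntpos <- ntpos + nchar(dna)
      pieces <- c(pieces, dna)
    }
  }
  dna <- paste(pieces, collapse = "")
  target <- paste(rep(protein, length(copies)), collapse = "")
  if (translateDNA(dna) != target)
    stop("rendered template does not translate to the target protein",
         call. = FALSE)

  idrep <- list()
  if (length(copies) >= 2) {
    ids <- utils::combn(length(copies), 2, function(ij) {
      percentIdentity(segDna[[as.character(copies[ij[1]])]],
                      segDna[[as.character(copies[ij[2]])]])
    })
    idrep$repeatIdentity <- as.numeric(ids)
  }
  if (!is.null(wtCds)) {
    wtSeg <- paste(vapply(seq_len(nrow(segments)), function(i)
      substr(wtCds, 3L * (segments$start[i] - 1L) + 1L,
             3L * segments$end[i]), character(1)), collapse = "")
    idrep$wtIdentity <- vapply(copies, function(cp)
      percentIdentity(segDna[[as.character(cp)]], wtSeg), numeric(1))
  }
  methods::new("DesignTemplate", dna = Biostrings::DNAString(dna),
               protein = target,
               annotations = do.call(rbind, ann),
               identityReport = idrep)
}

#' @rdname DesignTemplate-class
#' @export
setMethod("dnaSequence", "DesignTemplate",
          function(x) as.character(x@dna))

#' @rdname DesignTemplate-class
#' @export
setMethod("annotations", "DesignTemplate", function(x) x@annotations)

#' @rdname DesignTemplate-class
#' @export
setMethod("identityReport", "DesignTemplate", function(x) x@identityReport)

setMethod("show", "DesignTemplate", function(object) {
  cat("DesignTemplate: ", length(object@dna), " nt encoding ",
      nchar(object@protein), " residues (",
      length(unique(object@annotations$repeatId)), " repeat copies)\n",
      sep = "")
  if (!is.null(object@identityReport$repeatIdentity))
    cat("  repeat-vs-repeat identity over redesigned codons: ",
        paste(round(object@identityReport$repeatIdentity, 1),
              collapse = ", "), "%\n", sep = "")
})

#' Evaluate a rendered template for assembly-PCR suitability
#'
#' Recomputes the per-segment thermodynamic profile of the rendered
#' template, counts silent mutations per repeat copy against the wild-type
#' sequence (when available), and flags each segment against a configured
#' perfect-duplex Tm envelope — the annealing window required during PCR.
#'
#' @param template a [DesignTemplate-class].
#' @param params an [NNParameters-class] object.
#' @param wtCds optional wild-type coding sequence of one repeat unit.
#' @param tFrEnvelope length-2 numeric: acceptable `t_fr` range in degC
#'   (default `c(60, 80)`).
#' @return list with `segments` (per-segment profile and pass flag),
#'   `silentMutations` (per copy, when `wtCds` given), `repeatIdentity`,
#'   and overall `pass`.
#' @export
evaluateTemplate <- function(template, params = nnParameters(),
                             wtCds = NULL, tFrEnvelope = c(60, 80)) {
  ann <- annotations(template)
  des <- ann[ann$source == "design", , drop = FALSE]
  dna <- dnaSequence(template)
  seqs <- substring(dna, des$ntStart, des$ntEnd)
  wt <- if (!is.null(wtCds))
    vapply(seq_len(nrow(des)), function(i)
      substr(wtCds, 3L * (des$resStart[i] - 1L) + 1L,
             3L * des$resEnd[i]), character(1))
  prof <- do.call(rbind, lapply(seq_along(seqs), function(i)
    thermoProfile(seqs[i], wtWindow = if (!is.null(wt)) wt[i],
                  params = params)))
  segs <- cbind(des[c("segment", "repeatId", "resStart", "resEnd")], prof)
  segs$pass <- segs$t_fr >= tFrEnvelope[1] & segs$t_fr <= tFrEnvelope[2]

  out <- list(segments = segs)
  if (!is.null(wtCds)) {
    out$silentMutations <- vapply(
      split(seq_len(nrow(des)), des$repeatId), function(rows) {
        sum(vapply(rows, function(i) {
          a <- substring(seqs[i], seq(1, nchar(seqs[i]), 3),
                         seq(3, nchar(seqs[i]), 3))
          b <- substring(wt[i], seq(1, nchar(wt[i]), 3),
                         seq(3, nchar(wt[i]), 3))
          sum(a != b)
        }, numeric(1)))
      }, numeric(1))
  }
  out$repeatIdentity <- identityReport(template)$repeatIdentity
  ridOK <- is.null(out$repeatIdentity) || all(out$repeatIdentity < 100)
  out$pass <- all(segs$pass) && ridOK
  out
}
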