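# Independent oracles used by the tests.  These deliberately re-derive
# results by enumeration or direct arithmetic, sharing no code with the
# implementation paths they check.

BASES <- c("A", "C", "G", "T")

randomDna <- function(n) paste(sample(BASES, n, replace = TRUE),
                               collapse = "")

randomPeptide <- function(n) {
  aas <- setdiff(names(geneticCode()$degeneracy), character(0))
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# plain-R reverse complement, independent of Biostrings
rcOracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# recursive enumeration of synonymous sequences (no index arithmetic)
bruteEnumerate <- function(peptide) {
  tab <- geneticCode()$table
  aa <- strsplit(peptide, "")[[1]]
  seqs <- ""
  for (a in aa) seqs <- as.vector(t(outer(seqs, tab[[a]], paste0)))
  seqs
}

# Brute-force intermolecular duplex minimum free energy: enumerates every
# monotone set of Watson-Crick pairs with per-strand gaps <= maxLoop and
# sums the same parameter tables by direct lookup, accumulating the
# energy incrementally along the recursion.
bruteDuplex <- function(a, b, params, tempK = 310.15, maxLoop = 3) {
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])  # antiparallel
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(av); m <- length(bv)
  loopDS <- function(tab, size) -1000 * tab[size] / 310.15
  initH <- function(base) params@initDH[[
    if (base %in% c("A", "T")) "AT" else "GC"]]
  initS <- function(base) params@initDS[[
    if (base %in% c("A", "T")) "AT" else "GC"]]
  best <- list(dG = Inf)
  # close the structure at its last pair and record if optimal
  close <- function(i, dH, dS) {
    dH <- dH + initH(av[i]); dS <- dS + initS(av[i])
    dG <- dH - tempK * dS / 1000
    if (dG < best$dG) best <<- list(dH = dH, dS = dS, dG = dG)
  }
  extend <- function(i0, k0, dH, dS) {
    close(i0, dH, dS)
    for (i in (i0 + 1):min(n, i0 + 1 + maxLoop)) {
      if (i > n) break
      for (k in (k0 + 1):min(m, k0 + 1 + maxLoop)) {
        if (k > m) break
        if (comp[av[i]] != bv[k]) next
        gi <- i - i0 - 1; gk <- k - k0 - 1
        if (gi == 0 && gk == 0) {
          key <- paste0(av[i0], av[i])
          extend(i, k, dH + params@stackDH[[key]],
                 dS + params@stackDS[[key]])
        } else if (gi == 0 || gk == 0) {
          extend(i, k, dH, dS + loopDS(params@bulgeLoopDG37, gi + gk))
        } else {
          extend(i, k, dH, dS + loopDS(params@internalLoopDG37, gi + gk))
        }
      }
    }
  }
  any <- FALSE
  for (i in seq_len(n)) for (k in seq_len(m)) {
    if (comp[av[i]] == bv[k]) {
      any <- TRUE
      extend(i, k, initH(av[i]), initS(av[i]))
    }
  }
  if (!any) return(list(found = FALSE))
  c(best, found = TRUE)
}

# independent percentile: sort and linearly interpolate order statistics
percentileOracle <- function(x, q) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# independent validator for design paths (knows nothing of the DFS)
validPath <- function(path, candidates, segmentOrder, allowedPairs) {
  for (cp in unique(path$copy)) {
    sub <- path[path$copy == cp, , drop = FALSE]
    sub <- sub[match(segmentOrder, sub$segment), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1)) {
      jn <- paste0(sub$segment[i], "+", sub$segment[i + 1])
      ap <- allowedPairs[[jn]]
      if (is.null(ap)) next
      if (!any(ap[, 1] == sub$idx[i] & ap[, 2] == sub$idx[i + 1]))
        return(FALSE)
    }
  }
  for (lab in segmentOrder) {
    g <- path$group[path$segment == lab]
    if (anyDuplicated(g)) return(FALSE)
  }
  TRUE
}

# small toy design run shared by pipeline/acceptance tests
toyRun <- function(seed = 7, ...) {
  toy <- generateToyTR(10, 2, seed = seed)
  cfg <- designConfig(tFrMin = 55, overlapTmMin = 55, adjacentMin = 55,
                      tFrEnvelope = c(40, 95), seed = seed, ...)
  runDesign(toy$protein, list(c(1, nchar(toy$protein))), nRepeats = 2,
            wtCds = toy$wtCds, config = cfg)
}
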