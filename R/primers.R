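# Partitioning a template into alternating-strand assembly-PCR primers and
# validating the set by cross-hybridization.

#' Partition a template into an assembly-PCR primer set
#'
#' Tiles the template with alternating forward/reverse primers by greedy
#' extension: each junction overlap between consecutive primers is grown
#' until its perfect-duplex melting temperature reaches `overlapTmMin`,
#' then primer ends are trimmed or extended by at most 3 nt to land on a
#' G/C 3'-terminus, never exceeding `maxLen` bases per primer.  The
#' procedure is deterministic.
#'
#' @param template a [DesignTemplate-class] or a nucleotide string.
#' @param maxLen maximum primer length in bases (default 44).
#' @param overlapTmMin minimum overlap duplex Tm in degC (default 64).
#' @param params an [NNParameters-class] object.
#' @param namePrefix prefix for generated primer names (default "P").
#' @return A [PrimerSet-class].
#' @export
partitionPrimers <- function(template, maxLen = 44L, overlapTmMin = 64.0,
                             params = nnParameters(), namePrefix = "P") {
  tpl <- if (methods::is(template, "DesignTemplate"))
    dnaSequence(template) else .checkDna(template, "template")
  L <- nchar(tpl)
  if (L < 2L * 12L)
    stop("template too short to partition into two primers", call. = FALSE)
  base <- function(p) substr(tpl, p, p)
  gcAt <- function(p) base(p) %in% c("G", "C")

  # place the 3' end of a forward primer at or just before `e`
  adjustGC <- function(e, lower) {
    for (d in 0:3) if (e - d >= lower && gcAt(e - d)) return(e - d)
    stop("3'-terminus constraint unsatisfiable near template position ",
         e, " (no G/C within 3 nt)", call. = FALSE)
  }
  overlapTm <- function(s, e) {
    ov <- substr(tpl, s, e)
    as.numeric(hybridizationTm(ov, revComp(ov), params))
  }

  starts <- 1L
  ends <- adjustGC(min(maxLen, L), lower = 12L)
  strands <- "forward"
  while (ends[length(ends)] < L) {
    pe <- ends[length(ends)]
    ps <- starts[length(starts)]
    strand <- if (strands[length(strands)] == "forward") "reverse"
              else "forward"
    # shortest overlap suffix of the previous primer reaching overlapTmMin
    s <- NA_integer_
    for (cand in seq(pe - 7L, ps + 1L)) {
      if (overlapTm(cand, pe) >= overlapTmMin) { s <- cand; break }
    }
    if (is.na(s))
      stop("overlap Tm ", overlapTmMin, " degC unreachable within the ",
           "window ", ps, "-", pe, " (AT-rich stretch)", call. = FALSE)
    if (strand == "reverse") {
      # reverse primer's 3' end sits at template position s
      while (!gcAt(s) && s > ps + 1L && pe - s + 1L <= maxLen - 3L)
        s <- s - 1L
      if (!gcAt(s))
        stop("3'-terminus constraint unsatisfiable near template ",
             "position ", s, call. = FALSE)
    }
    e <- min(s + maxLen - 1L, L)
    if (strand == "forward" && e < L) e <- adjustGC(e, lower = s + 12L)
    if (e == L && strand == "forward" && !gcAt(L))
      stop("3'-terminus constraint unsatisfiable at the template end",
           call. = FALSE)
    if (e <= pe)
      stop("primer placement stalled at template position ", pe,
           call. = FALSE)
    starts <- c(starts, s); ends <- c(ends, e); strands <- c(strands, strand)
  }

  seqs <- vapply(seq_along(starts), function(i) {
    s <- substr(tpl, starts[i], ends[i])
    if (strands[i] == "reverse") revComp(s) else s
  }, character(1))
  prof <- thermoProfile(seqs, params = params)
  fold <- vapply(seqs, function(s) as.numeric(foldDG(s, 72, params)),
                 numeric(1))
  primers <- data.frame(
    name = paste0(namePrefix, ".", seq_along(seqs)),
    strand = strands, dna = seqs,
    start = starts, end = ends,
    t_ff = prof$t_ff, t_rr = prof$t_rr, t_fr = prof$t_fr,
    dg_fold_72 = unname(fold), stringsAsFactors = FALSE,
    row.names = NULL)

  ovl <- if (length(starts) > 1) {
    data.frame(
      left = primers$name[-nrow(primers)],
      right = primers$name[-1],
      start = starts[-1], end = ends[-length(ends)],
      sequence = substring(tpl, starts[-1], ends[-length(ends)]),
      stringsAsFactors = FALSE)
  } else data.frame(left = character(0), right = character(0),
                    start = integer(0), end = integer(0),
                    sequence = character(0))
  if (nrow(ovl))
    ovl$tm <- vapply(ovl$sequence, function(o)
      as.numeric(hybridizationTm(o, revComp(o), params)), numeric(1))

  ps <- methods::new("PrimerSet", primers = primers, overlaps = ovl,
                     crossMatrix = matrix(numeric(0), 0, 0),
                     template = tpl)
  ps@crossMatrix <- crossHybridizationMatrix(ps, params)
  ps
}

#' All-vs-all primer cross-hybridization matrix
#'
#' Hybridization Tm for every primer pair, each tested against the other's
#' given strand (the diagonal is the self-dimer Tm).  High values between
#' intended-adjacent primers drive correct assembly; high values elsewhere
#' indicate side products.
#'
#' @param x a [PrimerSet-class] or a data.frame with columns `name`, `dna`.
#' @param params an [NNParameters-class] object.
#' @return symmetric numeric matrix (degC) with primer names on both
#'   dimensions.
#' @export
crossHybridizationMatrix <- function(x, params = nnParameters()) {
  p <- if (methods::is(x, "PrimerSet")) primers(x) else x
  n <- nrow(p)
  m <- matrix(NA_real_, n, n, dimnames = list(p$name, p$name))
  for (i in seq_len(n)) {
    for (j in i:n) {
      tm <- as.numeric(hybridizationTm(p$dna[i], p$dna[j], params))
      m[i, j] <- tm; m[j, i] <- tm
    }
  }
  m
}

#' Validate an assembly primer set
#'
#' PASS iff every intended-adjacent primer pair hybridizes at or above
#' `adjacentMin`, every non-adjacent pair stays at or below `offtargetMax`,
#' and every primer is predicted linear at the extension temperature
#' (folding dG at 72 degC > 0).  Failures are report content, not errors.
#'
#' @param x a [PrimerSet-class], or a data.frame with columns `name`,
#'   `dna` whose row order is the intended adjacency.
#' @param adjacentMin minimum adjacent-pair hybridization Tm in degC
#'   (default 70).
#' @param offtargetMax maximum tolerated non-adjacent hybridization Tm in
#'   degC (default 50).
#' @param params an [NNParameters-class] object.
#' @return list with `pass`, `violations` (data.frame: `type`, `a`, `b`,
#'   `value`, `bound`), `crossMatrix`, and `note` for degenerate inputs.
#' @export
validateAssembly <- function(x, adjacentMin = 70.0, offtargetMax = 50.0,
                             params = nnParameters()) {
  p <- if (methods::is(x, "PrimerSet")) primers(x) else x
  m <- if (methods::is(x, "PrimerSet") && nrow(crossMatrix(x)))
    crossMatrix(x) else crossHybridizationMatrix(p, params)
  n <- nrow(p)
  viol <- list()
  note <- NULL
  if (n < 2) {
    note <- "single-primer set: adjacency checks are vacuous"
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        tm <- m[i, j]
        if (j == i + 1 && tm < adjacentMin)
          viol[[length(viol) + 1L]] <- data.frame(
            type = "adjacent-too-weak", a = p$name[i], b = p$name[j],
            value = tm, bound = adjacentMin)
        if (j > i + 1 && tm > offtargetMax)
          viol[[length(viol) + 1L]] <- data.frame(
            type = "offtarget-too-strong", a = p$name[i], b = p$name[j],
            value = tm, bound = offtargetMax)
      }
    }
  }
  fold <- if ("dg_fold_72" %in% names(p)) p$dg_fold_72 else
    vapply(p$dna, function(s) as.numeric(foldDG(s, 72, params)),
           numeric(1))
  bad <- which(fold <= 0)
  for (i in bad)
    viol[[length(viol) + 1L]] <- data.frame(
      type = "folded-at-extension", a = p$name[i], b = NA_character_,
      value = fold[i], bound = 0)
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(0), a = character(0), b = character(0),
               value = numeric(0), bound = numeric(0))
  list(pass = nrow(viol) == 0, violations = viol, crossMatrix = m,
       note = note)
}

#' Simulate overlap-extension assembly of a primer set
#'
#' Reconstructs the double-stranded product of an ordered
#' alternating-strand primer set by greedy merging of exact overlaps: each
#' primer (taken in template orientation) must share an exact terminal
#' overlap of at least `minOverlap` nt with the growing product.  Used both
#' to rebuild published templates from their printed primers and as an
#' independent check that a partitioned primer set reassembles its
#' template.
#'
#' @param sequences character vector of primer sequences, 5'->3' of their
#'   own strand, in assembly order.
#' @param strands "forward"/"reverse" per primer (default alternating,
#'   starting forward).
#' @param minOverlap minimum exact overlap in nt (default 10).
#' @return the assembled template string (template strand, 5'->3').
#' @export
assemblePrimers <- function(sequences,
                            strands = rep(c("forward", "reverse"),
                                          length.out = length(sequences)),
                            minOverlap = 10L) {
  stopifnot(length(sequences) >= 1,
            length(strands) == length(sequences))
  oriented <- mapply(function(s, st)
    if (st == "reverse") revComp(s) else .checkDna(s), sequences, strands)
  tpl <- oriented[[1]]
  for (s in oriented[-1]) {
    found <- 0L
    for (k in seq(min(nchar(tpl), nchar(s)), minOverlap)) {
      if (substr(tpl, nchar(tpl) - k + 1L, nchar(tpl)) ==
          substr(s, 1L, k)) { found <- k; break }
    }
    if (!found)
      stop("no exact overlap of >= ", minOverlap, " nt between ",
           "consecutive primers", call. = FALSE)
    tpl <- paste0(tpl, substr(s, found + 1L, nchar(s)))
  }
  tpl
}

#' @rdname PrimerSet-class
#' @export
setMethod("primers", "PrimerSet", function(x) x@primers)

#' @rdname PrimerSet-class
#' @export
setMethod("overlaps", "PrimerSet", function(x) x@overlaps)

#' @rdname PrimerSet-class
#' @export
setMethod("crossMatrix", "PrimerSet", function(x) x@crossMatrix)

#' @rdname PrimerSet-class
#' @export
setMethod("length", "PrimerSet", function(x) nrow(x@primers))

setMethod("show", "PrimerSet", function(object) {
  p <- object@primers
  cat("PrimerSet: ", nrow(p), " alternating-strand primers tiling ",
      nchar(object@template), " nt\n", sep = "")
  if (nrow(p)) {
    cat("  lengths ", min(nchar(p$dna)), "-", max(nchar(p$dna)),
        " nt", sep = "")
    if (nrow(object@overlaps))
      cat("; overlap Tm ", round(min(object@overlaps$tm), 1), "-",
          round(max(object@overlaps$tm), 1), " degC", sep = "")
    cat("\n")
  }
})

#' Write a primer order sheet
#'
#' TSV with name, 5'->3' sequence, strand, span and the thermodynamic
#' columns.
#'
#' @param x a [PrimerSet-class].
#' @param path output file.
#' @export
writePrimerSet <- function(x, path) {
  write.table(primers(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
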