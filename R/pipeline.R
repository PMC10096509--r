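# End-to-end redesign pipeline and its configuration.

#' Design-run configuration
#'
#' Collects every tunable of the redesign pipeline with the published
#' operating point as defaults: 5-7-residue segments; 50th-percentile
#' keep-below thresholds for the self-dimer and wild-type metrics
#' (`qFF`, `qRR`, `qWT`) with a 10th-percentile keep-above threshold for
#' the intended duplex (`qFR`; the alternative reported operating point
#' 0.2 is available as `preset = "results"`); similarity grouping at 80%
#' identity and cosine 0.9975 with 4 randomly retained groups per segment;
#' pair filtering discarding the top 20% homodimerizers with a fixed 80
#' degC duplex floor; 100 design paths; 44-nt primers with 64 degC
#' overlaps, validated at 70 degC adjacent / 50 degC off-target.
#'
#' @param preset "methods" (default, `qFR = 0.1`) or "results"
#'   (`qFR = 0.2`).
#' @param ... named overrides of any configuration field.
#' @return list of class `trdesign_config`.
#' @export
designConfig <- function(preset = c("methods", "results"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    minSegLen = 5L, maxSegLen = 7L,
    qFF = 0.5, qRR = 0.5, qWT = 0.5,
    qFR = if (preset == "results") 0.2 else 0.1,
    kGroups = 4L, idCut = 80.0, cosCut = 0.9975,
    qHomo = 0.2, tFrMin = 80.0,
    nPaths = 100L,
    primerMaxLen = 44L, overlapTmMin = 64.0,
    adjacentMin = 70.0, offtargetMax = 50.0,
    tFrEnvelope = c(60, 80),
    sodium = 1.0, ct = 1e-6, tmOffset = 0.0,
    junctionExclusions = character(0),
    seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "trdesign_config")
}

#' @rdname designConfig
#' @param config a `trdesign_config`.
#' @param path JSON file path.
#' @export
writeDesignConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname designConfig
#' @export
readDesignConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(designConfig, raw[setdiff(names(raw), "qFR")]) ->
    cfg
  cfg$qFR <- raw$qFR
  cfg
}

#' Run the full tandem-repeat redesign pipeline
#'
#' Executes the complete workflow on one repeat unit: segmentation of the
#' designated region(s), exhaustive synonymous enumeration, thermodynamic
#' profiling and percentile filtering, identity grouping and group
#' sampling, adjacent-pair joining and filtering, depth-first path search
#' under the repeat-dissimilarity constraint, template rendering and
#' evaluation, and (optionally) primer partitioning with cross-
#' hybridization validation.
#'
#' @param protein amino-acid sequence of one repeat unit.
#' @param regions list of `c(start, end)` residue ranges to redesign, or a
#'   segment data.frame from [segmentRegion()] to use as-is.
#' @param nRepeats number of tandem copies in the final construct
#'   (default 2).
#' @param wtCds optional wild-type coding sequence of the repeat unit
#'   (enables the \eqn{T_{WT}} screen); residues outside the designed
#'   regions are filled from it.
#' @param config a [designConfig()] list.
#' @param params optional [NNParameters-class]; built from `config`
#'   otherwise.
#' @param doPrimers also partition and validate primers (default TRUE).
#' @param verbose print per-stage progress to stderr.
#' @return list of class `trdesign_run` with elements `config`,
#'   `segments`, `candidates`, `segmentReport`, `junctionReport`, `paths`,
#'   `template` ([DesignTemplate-class]), `evaluation`, `primerSet`,
#'   `validation`.
#' @export
runDesign <- function(protein, regions, nRepeats = 2L, wtCds = NULL,
                      config = designConfig(), params = NULL,
                      doPrimers = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  params <- params %||% nnParameters(sodium = config$sodium,
                                     ct = config$ct,
                                     tmOffset = config$tmOffset)
  protein <- toupper(protein)

  segments <- if (is.data.frame(regions)) regions else {
    segs <- list()
    nextLabel <- 1L
    for (rg in regions) {
      s <- segmentRegion(protein, rg, config$minSegLen, config$maxSegLen,
                         firstLabel = LETTERS[nextLabel])
      nextLabel <- nextLabel + nrow(s)
      segs[[length(segs) + 1L]] <- s
    }
    do.call(rbind, segs)
  }
  # regions = maximal runs of contiguous segments (junctions live inside)
  segments <- segments[order(segments$start), , drop = FALSE]
  regionId <- cumsum(c(1L, as.integer(
    segments$start[-1] != segments$end[-nrow(segments)] + 1L)))

  candidates <- list()
  segRows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, , drop = FALSE]
    combos <- enumerateSynonymous(seg)
    wtw <- if (!is.null(wtCds)) wtWindow(wtCds, seg)
    prof <- thermoProfile(dnaSequences(combos), wtWindow = wtw,
                          params = params)
    keep <- filterCombinations(prof, config$qFF, config$qRR, config$qWT,
                               config$qFR, segment = seg$label)
    survivors <- which(keep)
    m <- identityMatrix(dnaSequences(combos)[survivors])
    groups <- assignGroups(m, config$idCut, config$cosCut)
    sampled <- sampleGroups(groups, config$kGroups,
                            seed = config$seed + i)
    sel <- survivors[sampled]
    candidates[[seg$label]] <- data.frame(
      idx = sel, dna = dnaSequences(combos)[sel],
      group = as.integer(groups)[sampled],
      t_fr = prof$t_fr[sel], stringsAsFactors = FALSE)
    cuts <- attr(keep, "cutoffs")
    segRows[[i]] <- data.frame(
      segment = seg$label, nCombos = length(combos),
      cut_t_ff = cuts[["t_ff"]], cut_t_rr = cuts[["t_rr"]],
      cut_t_fr = cuts[["t_fr"]],
      cut_t_wt = if ("t_wt" %in% names(cuts)) cuts[["t_wt"]] else NA_real_,
      nSurvivors = length(survivors),
      prunedFraction = attr(keep, "prunedFraction"),
      nGroups = length(unique(as.integer(groups))),
      nSampled = length(sel), stringsAsFactors = FALSE)
    say("segment ", seg$label, ": ", length(combos), " combinations, ",
        length(survivors), " survivors, ",
        segRows[[i]]$nGroups, " groups, ", length(sel), " carried")
  }
  segmentReport <- do.call(rbind, segRows)

  allowedPairs <- list()
  juncRows <- list()
  for (i in seq_len(nrow(segments) - 1L)) {
    if (regionId[i + 1L] != regionId[i]) next
    junction <- paste0(segments$label[i], "+", segments$label[i + 1L])
    if (junction %in% config$junctionExclusions) next
    pairs <- joinAdjacent(candidates[[segments$label[i]]]$dna,
                          candidates[[segments$label[i + 1L]]]$dna,
                          params)
    kept <- filterPairs(pairs, config$qHomo, config$tFrMin,
                        junction = junction)
    allowedPairs[[junction]] <- as.matrix(kept[c("left", "right")])
    juncRows[[length(juncRows) + 1L]] <- data.frame(
      junction = junction, nPairs = nrow(pairs),
      nSurvivors = nrow(kept),
      reductionFraction = attr(kept, "reductionFraction"),
      stringsAsFactors = FALSE)
    say("junction ", junction, ": ", nrow(pairs), " pairs, ",
        nrow(kept), " survive")
  }
  junctionReport <- if (length(juncRows)) do.call(rbind, juncRows) else
    data.frame()

  paths <- dfsPaths(candidates, segments$label, allowedPairs,
                    copies = nRepeats, nPaths = config$nPaths,
                    seed = config$seed + 1000L)
  say(length(paths), " design path(s) found")

  fixed <- NULL
  if (!is.null(wtCds)) {
    covered <- rep(FALSE, nchar(protein))
    for (i in seq_len(nrow(segments)))
      covered[segments$start[i]:segments$end[i]] <- TRUE
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    gap <- !runs$values
    if (any(gap))
      fixed <- data.frame(
        start = starts[gap], end = ends[gap],
        dna = vapply(which(gap), function(g)
          substr(wtCds, 3L * (starts[g] - 1L) + 1L, 3L * ends[g]),
          character(1)), stringsAsFactors = FALSE)
  }
  template <- renderTemplate(paths[[1]], protein, segments,
                             fixedRegions = fixed, wtCds = wtCds)
  evaluation <- evaluateTemplate(template, params, wtCds = wtCds,
                                 tFrEnvelope = config$tFrEnvelope)

  out <- list(config = config, segments = segments,
              candidates = candidates, segmentReport = segmentReport,
              junctionReport = junctionReport, paths = paths,
              template = template, evaluation = evaluation)
  if (doPrimers) {
    out$primerSet <- partitionPrimers(template, config$primerMaxLen,
                                      config$overlapTmMin, params)
    out$validation <- validateAssembly(out$primerSet,
                                       config$adjacentMin,
                                       config$offtargetMax, params)
    say("primer set: ", length(out$primerSet), " primers, validation ",
        if (out$validation$pass) "PASS" else "FAIL")
  }
  class(out) <- "trdesign_run"
  out
}

#' @export
print.trdesign_run <- function(x, ...) {
  cat("Tandem-repeat redesign run\n")
  cat("  segments:", nrow(x$segments), " paths:", length(x$paths), "\n")
  print(x$template)
  if (!is.null(x$primerSet)) print(x$primerSet)
  invisible(x)
}
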