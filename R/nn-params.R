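#' Construct a nearest-neighbor parameter set
#'
#' Loads the unified nearest-neighbor DNA stack table and loop penalty
#' schedule shipped with the package (tab-separated files under
#' `inst/extdata`, editable and swappable) and combines them with reaction
#' conditions into an [NNParameters-class] object.
#'
#' Defaults mirror the conditions commonly used by two-state melting web
#' services: 1.0 M monovalent salt, no divalents, total strand concentration
#' \eqn{C_T} = 1 uM.  The entropic salt correction (0.368 cal/mol/K per
#' stack times ln\[Na+\]) vanishes at 1 M.  `tmOffset` is an additive
#' calibration constant for reported melting temperatures, normally set via
#' [calibrateTmOffset()] against a reference primer table.
#'
#' @param sodium monovalent cation molarity (default 1.0).
#' @param ct total strand concentration in mol/L (default 1e-6).
#' @param maxLoop largest bulge/internal-loop extent per strand explored by
#'   the duplex dynamic program (default 10).
#' @param tmOffset additive Tm calibration offset in degC (default 0).
#' @param stacksFile,loopsFile override the shipped parameter tables.
#' @return An [NNParameters-class] object.
#' @examples
#' p <- nnParameters()
#' p@stackDH[["GC"]]
#' @export
nnParameters <- function(sodium = 1.0, ct = 1e-6, maxLoop = 10L,
                         tmOffset = 0,
                         stacksFile = NULL, loopsFile = NULL) {
  key <- paste(stacksFile %||% "", loopsFile %||% "")
  tabs <- .trdesign_cache$nn_tabs[[key]]
  if (is.null(tabs)) {
    stacksFile <- stacksFile %||%
      system.file("extdata", "nn_stacks.tsv", package = "trdesign",
                  mustWork = TRUE)
    loopsFile <- loopsFile %||%
      system.file("extdata", "nn_loops.tsv", package = "trdesign",
                  mustWork = TRUE)
    st <- read.delim(stacksFile, comment.char = "#")
    lo <- read.delim(loopsFile, comment.char = "#")
    # expand the (possibly sparse) loop table to contiguous sizes
    sizes <- seq_len(max(lo$size))
    interp <- function(col) stats::approx(lo$size, lo[[col]], xout = sizes,
                                          rule = 2)$y
    tabs <- list(
      stackDH = stats::setNames(st$dH, st$dinuc),
      stackDS = stats::setNames(st$dS, st$dinuc),
      hairpin = interp("hairpin"), bulge = interp("bulge"),
      internal = interp("internal"))
    if (is.null(.trdesign_cache$nn_tabs))
      .trdesign_cache$nn_tabs <- list()
    .trdesign_cache$nn_tabs[[key]] <- tabs
  }
  methods::new("NNParameters",
               stackDH = tabs$stackDH, stackDS = tabs$stackDS,
               initDH = c(AT = 2.3, GC = 0.1),
               initDS = c(AT = 4.1, GC = -2.8),
               symmetryDS = -1.4,
               hairpinLoopDG37 = tabs$hairpin,
               bulgeLoopDG37 = tabs$bulge,
               internalLoopDG37 = tabs$internal,
               sodium = sodium, ct = ct,
               maxLoop = as.integer(maxLoop), tmOffset = tmOffset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "NNParameters", function(object) {
  cat("NNParameters: unified nearest-neighbor DNA set\n",
      "  [Na+] = ", object@sodium, " M, C_T = ", object@ct,
      " M, maxLoop = ", object@maxLoop,
      ", Tm offset = ", round(object@tmOffset, 2), " degC\n", sep = "")
})

# internal: encode a DNA string as integers A=0 C=1 G=2 T=3
.encodeDna <- function(dna) {
  match(strsplit(dna, "")[[1]], c("A", "C", "G", "T")) - 1L
}

# stack vectors ordered for C++ indexing 4*first+second
.stackVectors <- function(params) {
  dinucs <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              paste0)))
  list(dH = unname(params@stackDH[dinucs]),
       dS = unname(params@stackDS[dinucs]))
}

# per-base terminal initiation vectors (A,C,G,T)
.initVectors <- function(params) {
  list(dH = unname(params@initDH[c("AT", "GC", "GC", "AT")]),
       dS = unname(params@initDS[c("AT", "GC", "GC", "AT")]))
}
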