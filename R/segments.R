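#' Dissect a repeat region into contiguous peptide segments
#'
#' Splits a residue range of the target protein into contiguous segments of
#' `minLen` to `maxLen` residues.  The automatic partitioner prefers
#' equal-as-possible lengths with longer segments first (29 residues with
#' lengths 5-7 gives 6+6+6+6+5); an explicit partition table (see
#' [readSegmentTable()]) overrides it so published segment boundaries can be
#' reproduced exactly.
#'
#' @param protein amino-acid string of the full target protein.
#' @param region integer vector `c(start, end)`, 1-based inclusive residue
#'   range to redesign.
#' @param minLen,maxLen allowed segment lengths (defaults 5 and 7).
#' @param labels optional character vector of segment labels; defaults to
#'   consecutive capital letters starting at `firstLabel`.
#' @param firstLabel first automatic label (default "A").
#' @param repeatId repeat-copy identifier stored on every segment
#'   ("shared" when both repeat copies reuse the same peptide).
#' @param partition optional data.frame with columns `label`, `start`,
#'   `end` giving an explicit partition of `region`.
#' @return data.frame with columns `label`, `start`, `end`, `aa`,
#'   `repeatId`; the concatenated `aa` reconstruct the region.
#' @examples
#' segmentRegion(strrep("A", 40), c(1, 29))$label # "A".."E"
#' @export
segmentRegion <- function(protein, region, minLen = 5L, maxLen = 7L,
                          labels = NULL, firstLabel = "A",
                          repeatId = "shared", partition = NULL) {
  aa <- .checkPeptide(protein)
  stopifnot(length(region) == 2)
  start <- as.integer(region[1]); end <- as.integer(region[2])
  if (start < 1 || end > length(aa) || start > end)
    stop("region out of range for the protein", call. = FALSE)
  if (!is.null(partition)) {
    lens <- partition$end - partition$start + 1L
    if (partition$start[1] != start ||
        partition$end[nrow(partition)] != end ||
        (nrow(partition) > 1 &&
         !all(partition$start[-1] == partition$end[-nrow(partition)] + 1L)))
      stop("explicit partition does not tile the region", call. = FALSE)
    seg <- data.frame(label = as.character(partition$label),
                      start = as.integer(partition$start),
                      end = as.integer(partition$end))
  } else {
    lens <- .partitionLengths(end - start + 1L, minLen, maxLen)
    ends <- start - 1L + cumsum(lens)
    starts <- c(start, head(ends, -1L) + 1L)
    if (is.null(labels))
      labels <- LETTERS[seq_along(lens) + match(firstLabel, LETTERS) - 1L]
    seg <- data.frame(label = labels, start = starts, end = ends)
  }
  seg$aa <- vapply(seq_len(nrow(seg)), function(i)
    paste(aa[seg$start[i]:seg$end[i]], collapse = ""), character(1))
  seg$repeatId <- repeatId
  seg
}

# equal-as-possible segment lengths in [minLen, maxLen], longer first
.partitionLengths <- function(n, minLen, maxLen) {
  stopifnot(minLen >= 2, minLen <= maxLen)
  if (n < minLen)
    stop("region of length ", n, " is not coverable by segments of ",
         minLen, "-", maxLen, " residues (residual length ", n, ")",
         call. = FALSE)
  kmin <- ceiling(n / maxLen) # fewest segments
  kmax <- n %/% minLen        # most segments
  for (k in seq(kmin, max(kmin, kmax))) {
    base <- n %/% k; extra <- n %% k
    lens <- c(rep(base + 1L, extra), rep(base, k - extra))
    if (all(lens >= minLen & lens <= maxLen)) return(as.integer(lens))
  }
  stop("region of length ", n, " is not coverable by segments of ",
       minLen, "-", maxLen, " residues (residual length ",
       n %% maxLen, ")", call. = FALSE)
}

#' Read / write explicit segment partition tables
#'
#' Tab-separated tables with columns `label`, `start`, `end` (1-based
#' inclusive residue coordinates); `#` lines are comments.
#'
#' @param path file path.
#' @return `readSegmentTable`: data.frame with columns `label`, `start`,
#'   `end`.
#' @export
readSegmentTable <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "start", "end")
  if (!all(need %in% names(tab)))
    stop("segment table must have columns label, start, end", call. = FALSE)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab[need]
}

#' @rdname readSegmentTable
#' @param segments data.frame as returned by [segmentRegion()].
#' @export
writeSegmentTable <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Wild-type DNA window spanning a segment
#'
#' Extracts the wild-type codons covering a segment's residue range from an
#' in-frame wild-type coding sequence (nucleotide positions
#' `3*(start-1)+1 .. 3*end`).
#'
#' @param wtCds in-frame wild-type coding DNA of the full protein.
#' @param segment one row of a segment data.frame (or any list with
#'   `start`, `end`, `aa`).
#' @return Nucleotide string of length `3 * segment length`.
#' @export
wtWindow <- function(wtCds, segment) {
  wtCds <- .checkDna(wtCds, "wtCds")
  s <- as.integer(segment$start); e <- as.integer(segment$end)
  if (nchar(wtCds) %% 3 != 0 || nchar(wtCds) < 3L * e)
    stop("wild-type CDS is out of frame or shorter than the segment",
         call. = FALSE)
  win <- substr(wtCds, 3L * (s - 1L) + 1L, 3L * e)
  if (!is.null(segment$aa) && translateDNA(win) != segment$aa)
    stop("wild-type window does not translate to the segment peptide",
         call. = FALSE)
  win
}
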