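# File I/O: FASTA sequences, configuration JSON, TSV reports, GFF3
# annotations.

#' Read a single-record protein or DNA FASTA file
#'
#' Permissive on read (case, wrapping); returns the first record as an
#' uppercase string.
#'
#' @param path FASTA file.
#' @return sequence string.
#' @export
readProteinFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (!length(x)) stop("empty FASTA: ", path, call. = FALSE)
  toupper(as.character(x[[1]]))
}

#' @rdname readProteinFasta
#' @export
readDnaFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("empty FASTA: ", path, call. = FALSE)
  toupper(as.character(x[[1]]))
}

#' Write a sequence as single-record FASTA
#'
#' Uppercase, 60-column wrapped.
#'
#' @param seq sequence string.
#' @param name record name.
#' @param path output file.
#' @param type "DNA" or "AA".
#' @export
writeFasta <- function(seq, name, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA")
    Biostrings::DNAStringSet(stats::setNames(toupper(seq), name))
  else
    Biostrings::AAStringSet(stats::setNames(toupper(seq), name))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write template annotations as GFF3
#'
#' Per-codon-run provenance (segment label, repeat copy, similarity group,
#' design vs fixed origin) as GFF3 features on the template sequence.
#' Requires the optional GenomicRanges/rtracklayer packages.
#'
#' @param template a [DesignTemplate-class].
#' @param path output file.
#' @param seqname sequence name used in the GFF (default "template").
#' @export
writeTemplateGFF <- function(template, path, seqname = "template") {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE))
    stop("writing GFF3 requires GenomicRanges and rtracklayer",
         call. = FALSE)
  ann <- annotations(template)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(ann$ntStart, ann$ntEnd),
    strand = "+",
    type = ifelse(ann$source == "design", "redesigned_segment",
                  "fixed_region"),
    segment = ann$segment, repeatId = ann$repeatId,
    group = ann$group, combination = ann$combination)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a per-segment run report
#'
#' TSV analogue of a per-segment threshold table: resolved cutoffs,
#' candidate counts before/after filtering, group counts.
#'
#' @param report data.frame (one row per segment) as produced by
#'   [runDesign()]'s `segmentReport`.
#' @param path output file.
#' @export
writeSegmentReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
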