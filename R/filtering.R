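# Percentile pruning of codon combinations and identity-graph grouping.

#' Linear-interpolation percentile threshold
#'
#' Percentile of a set of segment metrics, computed by linear interpolation
#' between order statistics (`stats::quantile` type 7, the documented
#' method), so that resolved per-segment cutoffs are reproducible from the
#' same candidate list.
#'
#' @param values numeric vector (e.g. per-combination Tm values).
#' @param q fraction in \[0, 1\].
#' @return the threshold value.
#' @export
percentileThreshold <- function(values, q) {
  stopifnot(length(values) > 0, q >= 0, q <= 1)
  unname(stats::quantile(values, q, type = 7, names = FALSE))
}

#' Percentile-based pruning of codon combinations
#'
#' Resolves the four percentile thresholds against this segment's own
#' profile distribution and keeps a combination iff
#' `t_ff <= cut(qFF)`, `t_rr <= cut(qRR)`, `t_wt <= cut(qWT)` (when a
#' wild-type column is present) and `t_fr >= cut(qFR)`: self-dimerization
#' and wild-type cross-hybridization are minimized while hybridization with
#' the intended reverse complement is maximized.  Survivors keep their input
#' order.
#'
#' @param profiles data.frame from [thermoProfile()] (columns `t_ff`,
#'   `t_rr`, `t_fr`, optionally `t_wt`).
#' @param qFF,qRR,qWT keep-at-or-below percentiles (defaults 0.5).
#' @param qFR keep-at-or-above percentile (default 0.1; 0.2 is an
#'   alternative reported operating point, see [designConfig()]).
#' @param segment optional segment label used in error messages.
#' @return logical vector of survivors with attributes `cutoffs` (the
#'   resolved degC values) and `prunedFraction`.
#' @export
filterCombinations <- function(profiles, qFF = 0.5, qRR = 0.5, qWT = 0.5,
                               qFR = 0.1, segment = "?") {
  cut_ff <- percentileThreshold(profiles$t_ff, qFF)
  cut_rr <- percentileThreshold(profiles$t_rr, qRR)
  cut_fr <- percentileThreshold(profiles$t_fr, qFR)
  keep <- profiles$t_ff <= cut_ff & profiles$t_rr <= cut_rr &
    profiles$t_fr >= cut_fr
  cuts <- c(t_ff = cut_ff, t_rr = cut_rr, t_fr = cut_fr)
  if (!is.null(profiles$t_wt) && !all(is.na(profiles$t_wt))) {
    cut_wt <- percentileThreshold(profiles$t_wt, qWT)
    keep <- keep & profiles$t_wt <= cut_wt
    cuts <- c(cuts, t_wt = cut_wt)
  }
  if (!any(keep))
    stop("segment ", segment, " exhausted: no combination passes the ",
         "thermodynamic thresholds", call. = FALSE)
  structure(keep, cutoffs = cuts,
            prunedFraction = 1 - mean(keep))
}

#' Ungapped percent sequence identity
#'
#' `100 * matches / length` between two equal-length sequences (candidates
#' for one segment are positionally comparable by construction, so no gaps
#' are considered).
#'
#' @param a,b equal-length nucleotide strings.
#' @return identity in percent.
#' @examples
#' percentIdentity("ATGAAA", "ATGAAG") # 83.33
#' @export
percentIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length", call. = FALSE)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  100 * sum(av == bv) / length(av)
}

#' Pairwise percent-identity matrix
#'
#' @param dna character vector of equal-length sequences.
#' @return symmetric numeric matrix with 100 on the diagonal.
#' @export
identityMatrix <- function(dna) {
  n <- length(dna)
  stopifnot(n >= 1)
  if (length(unique(nchar(dna))) != 1)
    stop("sequences must have equal length", call. = FALSE)
  chars <- do.call(rbind, strsplit(dna, ""))
  m <- matrix(100, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      eq <- chars[(i + 1):n, , drop = FALSE] ==
        matrix(chars[i, ], n - i, ncol(chars), byrow = TRUE)
      v <- 100 * rowSums(eq) / ncol(chars)
      m[i, (i + 1):n] <- v
      m[(i + 1):n, i] <- v
    }
  }
  m
}

#' Cosine similarity of two identity-profile vectors
#'
#' @param u,v equal-length non-zero numeric vectors.
#' @return `dot(u, v) / (|u| |v|)`, in \[-1, 1\].
#' @export
cosineSimilarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Group codon combinations by shared sequence identity
#'
#' Two combinations are joined when their pairwise identity is at least
#' `idCut` percent and their percent-identity profiles against the rest of
#' the candidate list agree (cosine similarity at least `cosCut`).  Profile
#' vectors are the full matrix row with the vector's own diagonal entry
#' removed.  Joins are closed transitively (connected components of the
#' join graph), and each group is named by its smallest member index, so
#' the partition is deterministic.
#'
#' @param m identity matrix from [identityMatrix()].
#' @param idCut identity threshold in percent (default 80).
#' @param cosCut cosine threshold (default 0.9975).
#' @return integer vector: group id (smallest member index) per
#'   combination; `attr(, "groups")` lists members per group.
#' @export
assignGroups <- function(m, idCut = 80.0, cosCut = 0.9975) {
  n <- nrow(m)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (m[i, j] < idCut) next
        if (cosineSimilarity(m[i, -i], m[j, -j]) < cosCut) next
        edges <- c(edges, i, j)
      }
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  ids <- vapply(split(seq_len(n), comp), min, integer(1))
  grp <- ids[as.character(comp)]
  structure(as.integer(grp),
            groups = split(seq_len(n), grp))
}

#' Randomly sample similarity groups for a segment
#'
#' Keeps the combinations belonging to `k` groups chosen uniformly without
#' replacement (all groups when fewer than `k` exist); used to bound the
#' combinatorial space carried into pair joining.
#'
#' @param groups integer vector from [assignGroups()].
#' @param k number of groups to keep (default 4).
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the global RNG.
#' @return logical vector of retained combinations, with attribute
#'   `selectedGroups`.
#' @export
sampleGroups <- function(groups, k = 4L, seed) {
  stopifnot(k >= 1)
  ids <- sort(unique(as.integer(groups)))
  sel <- if (length(ids) <= k) ids else
    withr::with_seed(seed, sort(sample(ids, k)))
  structure(as.integer(groups) %in% sel, selectedGroups = sel)
}
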