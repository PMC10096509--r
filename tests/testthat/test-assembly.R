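# Pair joining, pair filtering, depth-first path search, template
# rendering and evaluation.

params <- nnParameters()

test_that("adjacent joining takes the Cartesian product and stays silent", {
  left <- bruteEnumerate("MI")[1:3]
  right <- bruteEnumerate("VT")[1:4]
  pairs <- joinAdjacent(left, right, params)
  expect_equal(nrow(pairs), 12L)
  expect_true(all(vapply(pairs$dna, translateDNA, character(1)) == "MIVT"))
  expect_error(joinAdjacent(character(0), right, params), "exhausted")
})

test_that("longer perfect duplexes melt higher than their parts", {
  withr::with_seed(12, {
    for (i in 1:5) {
      a <- randomDna(15); b <- randomDna(15)
      tmJoined <- as.numeric(hybridizationTm(paste0(a, b),
                                             revComp(paste0(a, b)),
                                             params))
      tmA <- as.numeric(hybridizationTm(a, revComp(a), params))
      tmB <- as.numeric(hybridizationTm(b, revComp(b), params))
      expect_gte(tmJoined, max(tmA, tmB))
    }
  })
})

test_that("pair filtering discards top homodimerizers and low-Tm pairs", {
  withr::with_seed(27, {
    pairs <- data.frame(left = 1:20, right = 1:20,
                        dna = replicate(20, randomDna(30)),
                        t_ff = runif(20, -40, 40),
                        t_rr = runif(20, -40, 40),
                        t_fr = runif(20, 70, 95))
    kept <- filterPairs(pairs, qHomo = 0.2, tFrMin = 80)
    cut_ff <- percentileOracle(pairs$t_ff, 0.8)
    cut_rr <- percentileOracle(pairs$t_rr, 0.8)
    expected <- pairs$t_ff <= cut_ff & pairs$t_rr <= cut_rr &
      pairs$t_fr >= 80
    expect_equal(kept$left, pairs$left[expected])
    # vacuous thresholds keep all
    expect_equal(nrow(filterPairs(pairs, qHomo = 0, tFrMin = -Inf)), 20L)
    expect_error(filterPairs(pairs, qHomo = 0, tFrMin = 1000,
                             junction = "A+B"),
                 "junction A\\+B exhausted")
  })
})

# a small hand-checkable search instance: two segments, two groups each
tinyCandidates <- function() {
  list(A = data.frame(idx = 1:4, dna = c("AAACCC", "AAACCG", "GGGTTT",
                                         "GGGTTC"),
                      group = c(1L, 1L, 3L, 3L), t_fr = c(60, 61, 62, 63)),
       B = data.frame(idx = 1:4, dna = c("CCCAAA", "CCCAAG", "TTTGGG",
                                         "TTTGGC"),
                      group = c(1L, 1L, 3L, 3L), t_fr = c(60, 61, 62, 63)))
}

test_that("the DFS finds exactly the hand-enumerable valid paths", {
  cand <- tinyCandidates()
  allowed <- list("A+B" = cbind(rep(1:4, each = 4), rep(1:4, 4)))
  paths <- dfsPaths(cand, c("A", "B"), allowed, copies = 2,
                    nPaths = 1000, seed = 3)
  # brute-force enumeration of valid assignments
  valid <- 0L
  for (a1 in 1:4) for (b1 in 1:4) for (a2 in 1:4) for (b2 in 1:4) {
    if (cand$A$group[a1] != cand$A$group[a2] &&
        cand$B$group[b1] != cand$B$group[b2]) valid <- valid + 1L
  }
  expect_equal(length(paths), valid)  # 8 * 8 = 64
  keys <- vapply(paths, function(p) paste(p$idx, collapse = "-"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(vapply(paths, validPath, logical(1),
                         cand, c("A", "B"), allowed)))
})

test_that("junction constraints prune the DFS and propagate to paths", {
  cand <- tinyCandidates()
  # only same-index pairs survive the junction
  allowed <- list("A+B" = cbind(1:4, 1:4))
  paths <- dfsPaths(cand, c("A", "B"), allowed, copies = 2,
                    nPaths = 1000, seed = 3)
  expect_true(all(vapply(paths, validPath, logical(1),
                         cand, c("A", "B"), allowed)))
  expect_equal(length(paths), 8L)  # 4 choices x 2 valid partners
})

test_that("a duplicated segment with a single group is infeasible", {
  cand <- tinyCandidates()
  cand$A$group <- 1L
  expect_error(dfsPaths(cand, c("A", "B"),
                        list("A+B" = cbind(rep(1:4, each = 4),
                                           rep(1:4, 4))),
                        copies = 2, nPaths = 10, seed = 1),
               "design infeasible")
})

test_that("the DFS is deterministic under a fixed seed", {
  cand <- tinyCandidates()
  allowed <- list("A+B" = cbind(rep(1:4, each = 4), rep(1:4, 4)))
  p1 <- dfsPaths(cand, c("A", "B"), allowed, copies = 2, nPaths = 1,
                 seed = 11)
  p2 <- dfsPaths(cand, c("A", "B"), allowed, copies = 2, nPaths = 1,
                 seed = 11)
  expect_identical(p1, p2)
})

test_that("rendering splices, translates and reports identities", {
  pep <- "MKVTLYDAGH"
  seg <- segmentRegion(pep, c(1, 10))
  combos <- lapply(seq_len(nrow(seg)), function(i)
    enumerateSynonymous(seg[i, ]))
  path <- do.call(rbind, lapply(1:2, function(cp)
    do.call(rbind, lapply(seq_len(nrow(seg)), function(i)
      data.frame(copy = cp, segment = seg$label[i], idx = cp,
                 group = cp,
                 dna = dnaSequences(combos[[i]])[cp])))))
  tpl <- renderTemplate(path, pep, seg)
  expect_equal(length(Biostrings::DNAString(dnaSequence(tpl))), 60L)
  expect_equal(translateDNA(dnaSequence(tpl)), strrep(pep, 2))
  expect_equal(nrow(annotations(tpl)), 4L)

  # identical combinations in both copies give 100% repeat identity
  path100 <- path
  path100$dna <- rep(path$dna[path$copy == 1], 2)
  path100$idx <- 1L
  tpl100 <- renderTemplate(path100, pep, seg)
  expect_equal(identityReport(tpl100)$repeatIdentity, 100)

  # residues not covered by segments or fixed regions are an error
  segGap <- seg[1, , drop = FALSE]
  expect_error(renderTemplate(path[path$segment == "A", , drop = FALSE],
                              pep, segGap),
               "coverage gap")
})

test_that("template evaluation counts silent mutations and flags failures", {
  pep <- "MKVTLYDAGH"
  wt <- backTranslate(pep)
  seg <- segmentRegion(pep, c(1, 10))
  combos <- lapply(seq_len(nrow(seg)), function(i)
    enumerateSynonymous(seg[i, ]))
  # wild-type duplicated verbatim: zero silent mutations, FAIL
  pathWT <- do.call(rbind, lapply(1:2, function(cp)
    data.frame(copy = cp, segment = seg$label, idx = 1L, group = 1L,
               dna = vapply(seq_len(nrow(seg)), function(i)
                 wtWindow(wt, seg[i, ]), character(1)))))
  tplWT <- renderTemplate(pathWT, pep, seg, wtCds = wt)
  evWT <- evaluateTemplate(tplWT, params, wtCds = wt)
  expect_equal(unname(evWT$silentMutations), c(0, 0))
  expect_equal(identityReport(tplWT)$repeatIdentity, 100)
  expect_false(evWT$pass)

  # a two-codon toy with hand-counted mutations
  segB <- data.frame(label = "A", start = 1L, end = 5L,
                     aa = substr(pep, 1, 5), repeatId = "shared")
  alt <- dnaSequences(enumerateSynonymous(segB[1, ]))
  pick <- alt[alt != wtWindow(wt, segB[1, ])][1]
  path2 <- rbind(
    data.frame(copy = 1, segment = "A", idx = 1L, group = 1L,
               dna = wtWindow(wt, segB[1, ])),
    data.frame(copy = 2, segment = "A", idx = 2L, group = 2L,
               dna = pick))
  tpl2 <- renderTemplate(path2, substr(pep, 1, 5), segB, wtCds = substr(wt, 1, 15))
  ev2 <- evaluateTemplate(tpl2, params, wtCds = substr(wt, 1, 15))
  handCount <- sum(vapply(seq(1, 13, 3), function(i)
    substr(pick, i, i + 2) != substr(wt, i, i + 2), logical(1)))
  expect_equal(unname(ev2$silentMutations),
               c(0, handCount))
})
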