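# Percentile pruning, identity matrices, cosine grouping, group sampling.

test_that("percentile thresholds interpolate order statistics", {
  expect_equal(percentileThreshold(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(percentileThreshold(10, 0.2), 10)
  expect_equal(percentileThreshold(10, 0.9), 10)
  expect_error(percentileThreshold(numeric(0), 0.5))
  withr::with_seed(21, {
    x <- runif(100)
    for (q in c(0, 0.2, 0.37, 0.5, 0.9, 1))
      expect_equal(percentileThreshold(x, q), percentileOracle(x, q),
                   tolerance = 1e-12)
  })
})

test_that("combination filtering applies the four inequalities", {
  withr::with_seed(33, {
    prof <- data.frame(t_ff = runif(10, -50, 50),
                       t_rr = runif(10, -50, 50),
                       t_fr = runif(10, 40, 90),
                       t_wt = runif(10, -50, 50))
    keep <- filterCombinations(prof, 0.5, 0.5, 0.5, 0.1)
    # brute-force re-application with the independent percentile oracle
    expected <- prof$t_ff <= percentileOracle(prof$t_ff, 0.5) &
      prof$t_rr <= percentileOracle(prof$t_rr, 0.5) &
      prof$t_wt <= percentileOracle(prof$t_wt, 0.5) &
      prof$t_fr >= percentileOracle(prof$t_fr, 0.1)
    expect_equal(as.logical(keep), expected)

    # vacuous thresholds keep everything
    all_in <- filterCombinations(prof, 1, 1, 1, 0)
    expect_true(all(all_in))

    # impossible combination of thresholds names the segment
    prof2 <- data.frame(t_ff = 1:4, t_rr = 1:4, t_fr = c(1, 4, 4, 4))
    expect_error(filterCombinations(prof2, 0, 0, 0, 1, segment = "Q"),
                 "segment Q exhausted")
  })
})

test_that("filtering survivors again with resolved cutoffs is idempotent", {
  withr::with_seed(14, {
    prof <- data.frame(t_ff = runif(40, -50, 50),
                       t_rr = runif(40, -50, 50),
                       t_fr = runif(40, 40, 90))
    keep <- filterCombinations(prof, qWT = 1)
    cuts <- attr(keep, "cutoffs")
    surv <- prof[keep, ]
    again <- surv$t_ff <= cuts[["t_ff"]] & surv$t_rr <= cuts[["t_rr"]] &
      surv$t_fr >= cuts[["t_fr"]]
    expect_true(all(again))
  })
})

test_that("percent identity counts matching positions", {
  expect_equal(percentIdentity("ATGAAA", "ATGAAA"), 100)
  expect_equal(percentIdentity("ATGAAA", "ATGAAG"), 100 * 5 / 6,
               tolerance = 1e-9)
  expect_error(percentIdentity("ATG", "ATGC"), "equal length")
  withr::with_seed(8, {
    a <- randomDna(30); b <- randomDna(30)
    expect_equal(percentIdentity(a, b), percentIdentity(b, a))
  })
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  expect_equal(identityMatrix("ATG"), matrix(100, 1, 1))
  trio <- c("AAAAAA", "AAATAA", "CCCCCC")
  m <- identityMatrix(trio)
  # hand-counted values
  expect_equal(m[1, 2], 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(m[1, 3], 0)
  expect_equal(m[2, 3], 0)
  expect_equal(diag(m), rep(100, 3))
  withr::with_seed(4, {
    r <- vapply(1:6, function(i) randomDna(12), character(1))
    mr <- identityMatrix(r)
    expect_equal(mr, t(mr))
  })
})

test_that("cosine similarity is the normalized dot product", {
  expect_equal(cosineSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero")
  withr::with_seed(2, {
    u <- runif(10); v <- runif(10)
    expect_equal(cosineSimilarity(u, v),
                 sum(u * v) / sqrt(sum(u^2) * sum(v^2)),
                 tolerance = 1e-12)
  })
})

test_that("grouping joins similar combinations into components", {
  # all identical: one group
  g1 <- assignGroups(identityMatrix(rep("ACGTAC", 4)))
  expect_equal(length(unique(g1)), 1L)
  # pairwise dissimilar: every combination its own group
  g2 <- assignGroups(identityMatrix(c("AAAAAA", "CCCCCC", "GGGGGG",
                                      "TTTTTT")))
  expect_equal(length(unique(g2)), 4L)
  # one similar trio plus three mutually distinct sequences: 4 clusters
  six <- c(rep("ACGTACGTACGT", 3),
           "TTTTTTTTTTTT", "GGGGGGGGGGGG", "CACACACACACA")
  g3 <- assignGroups(identityMatrix(six))
  expect_equal(length(unique(g3)), 4L)
  expect_equal(g3[1], g3[2])
  expect_equal(g3[1], g3[3])
})

test_that("grouping is invariant under input permutation", {
  withr::with_seed(19, {
    base <- bruteEnumerate("VTL")
    dna <- sample(base, 24)
    g <- assignGroups(identityMatrix(dna))
    perm <- sample(seq_along(dna))
    gp <- assignGroups(identityMatrix(dna[perm]))
    # same partition up to relabeling
    expect_equal(outer(g[perm], g[perm], "=="), outer(gp, gp, "=="),
                 ignore_attr = TRUE)
  })
})

test_that("group sampling is uniform, seeded and total when k exceeds groups", {
  groups <- rep(1:3, each = 2)
  all3 <- sampleGroups(groups, k = 4, seed = 1)
  expect_true(all(all3))
  g8 <- rep(1:8, each = 3)
  s1 <- sampleGroups(g8, k = 4, seed = 99)
  s2 <- sampleGroups(g8, k = 4, seed = 99)
  expect_identical(s1, s2)
  counts <- integer(8)
  for (s in 1:2000) {
    sel <- attr(sampleGroups(g8, k = 4, seed = s), "selectedGroups")
    counts[sel] <- counts[sel] + 1L
  }
  expect_true(all(abs(counts / 2000 - 0.5) < 0.05))
})
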