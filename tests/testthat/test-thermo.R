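# Nearest-neighbor duplex/hairpin engine and two-state melting.

params <- nnParameters()

test_that("parameter set reconstructs published dG37 within 0.05 kcal/mol", {
  # unified-set dG37 for the ten unique stacks
  dg37 <- c(AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45, GT = -1.44,
            CT = -1.28, GA = -1.30, CG = -2.17, GC = -2.24, GG = -1.84)
  got <- params@stackDH[names(dg37)] - 310.15 *
    params@stackDS[names(dg37)] / 1000
  expect_true(all(abs(got - dg37) < 0.05))
})

test_that("a perfect duplex equals the hand-summed stack total", {
  # CGTTGA / TCAACG: stacks CG, GT, TT, TG, GA plus one G.C and one A.T end
  dh <- -10.6 - 8.4 - 7.9 - 8.5 - 8.2 + 0.1 + 2.3
  ds <- -27.2 - 22.4 - 22.2 - 22.7 - 22.2 - 2.8 + 4.1
  d <- duplexMFE("CGTTGA", revComp("CGTTGA"), params)
  expect_equal(d$dH, dh)
  expect_equal(d$dS, ds)
  expect_equal(d$npairs, 6L)
  # Tm closed form, independent arithmetic
  expect_equal(d$tm, 1000 * dh / (ds + 1.9872 * log(1e-6 / 4)) - 273.15,
               tolerance = 1e-10)
})

test_that("non-pairable strands are flagged as having no duplex", {
  d <- duplexMFE("AAAAAAAA", "AAAAAAAA", params)
  expect_false(d$found)
  tm <- hybridizationTm("AAAAAAAA", "AAAAAAAA", params)
  expect_equal(as.numeric(tm), -273.15)
  expect_equal(attr(tm, "flag"), "no stable duplex")
})

test_that("palindromes behave identically as homodimer or heterodimer", {
  pal <- "GGAATTCC"
  expect_equal(revComp(pal), pal)
  a <- duplexMFE(pal, pal, params)
  b <- duplexMFE(pal, revComp(pal), params)
  expect_equal(a$dH, b$dH)
  expect_equal(a$dS, b$dS)
  expect_equal(a$tm, b$tm)
})

test_that("two-state Tm follows the formula and its degeneracies", {
  # worked example recomputed with independent arithmetic
  dh <- -57.8; ds <- -164.6; ct <- 1e-4
  expected <- 1000 * dh / (ds + 1.9872 * log(ct / 4)) - 273.15
  expect_equal(twoStateTm(dh, ds, ct = ct, params = params), expected,
               tolerance = 1e-12, ignore_attr = TRUE)
  # doubling concentration strictly raises Tm for a favorable duplex
  expect_gt(twoStateTm(dh, ds, ct = 2e-4, params = params),
            twoStateTm(dh, ds, ct = 1e-4, params = params))
  # degenerate enthalpy: no transition
  t0 <- twoStateTm(0, ds, ct = ct, params = params)
  expect_equal(as.numeric(t0), -273.15)
  expect_equal(attr(t0, "flag"), "no transition")
})

test_that("dG at the melting temperature equals the concentration term", {
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- randomDna(20)
      d <- duplexMFE(x, revComp(x), params)
      tmK <- d$tm + 273.15
      conc <- 1.9872 * tmK * log(params@ct / 4) / 1000
      expect_equal(d$dH - tmK * d$dS / 1000, conc, tolerance = 1e-6)
    }
  })
})

test_that("duplex DP equals brute-force enumeration on short pairs", {
  p3 <- nnParameters(maxLoop = 3)
  withr::with_seed(42, {
    cases <- c(
      list(c("ACGTACGT", rcOracle("ACGTACGT")), c("GGGGG", "CCCCC"),
           c("ACGCGT", "ACGCGT")),
      lapply(1:25, function(i) c(randomDna(sample(4:9, 1)),
                                 randomDna(sample(4:9, 1)))))
    for (cs in cases) {
      dp <- duplexMFE(cs[1], cs[2], p3)
      bf <- bruteDuplex(cs[1], cs[2], p3, maxLoop = 3)
      expect_equal(dp$found, bf$found, info = paste(cs, collapse = "/"))
      if (bf$found) {
        expect_equal(dp$dGatT, bf$dG, tolerance = 1e-9,
                     info = paste(cs, collapse = "/"))
        expect_equal(dp$dH, bf$dH, tolerance = 1e-9)
      }
    }
  })
})

test_that("hybridization Tm is symmetric and dominated by the perfect duplex", {
  withr::with_seed(9, {
    for (i in 1:25) {
      x <- randomDna(sample(15:45, 1))
      y <- randomDna(sample(15:45, 1))
      expect_equal(as.numeric(hybridizationTm(x, y, params)),
                   as.numeric(hybridizationTm(y, x, params)))
      r <- revComp(x)
      expect_gte(as.numeric(hybridizationTm(x, r, params)),
                 as.numeric(hybridizationTm(x, x, params)))
    }
  })
})

test_that("hairpin folding matches a hand-built stem-loop and its edge cases", {
  a <- foldDG("AAAAAAAAAA", 72, params)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "linear"))
  # GGGGAAAACCCC: 4-bp stem (three GG stacks), 4-nt loop
  dh <- 3 * -8.0
  ds <- 3 * -19.9 - 3.5 * 1000 / 310.15
  g25 <- foldDG("GGGGAAAACCCC", 25, params)
  expect_equal(as.numeric(g25), dh - 298.15 * ds / 1000, tolerance = 1e-9)
  expect_lt(as.numeric(g25), 0)
  # the same hairpin is destabilized but still reported at 72 degC
  expect_gt(as.numeric(foldDG("GGGGAAAACCCC", 72, params)),
            as.numeric(g25))
  # published assembly primers stay linear at the extension temperature
  expect_gt(as.numeric(foldDG("CCAGTAGTAGGTTGAGGC", 72, params)), 0)
})

test_that("profiles carry the four metrics and are bit-stable", {
  combos <- enumerateSynonymous(list(label = "X", start = 1L, end = 5L,
                                     aa = "MKPVT"))
  dna <- dnaSequences(combos)[1:5]
  wt <- backTranslate("MKPVT")
  p1 <- thermoProfile(dna, wtWindow = wt, params = params)
  p2 <- thermoProfile(dna, wtWindow = wt, params = params)
  expect_identical(p1, p2)
  expect_named(p1, c("t_ff", "t_rr", "t_fr", "t_wt"))
  # a combination identical to the wild type has t_wt == t_fr
  pwt <- thermoProfile(wt, wtWindow = wt, params = params)
  expect_equal(pwt$t_wt, pwt$t_fr)
})

test_that("calibration fits a single additive offset on perfect-duplex Tm", {
  seqs <- c("CCAGTAGTAGGTTGAGGC", "GAGCGGACCAGTAATGATAGGGATCC",
            "GCTCTGTTTGCCCGCCAGTTG")
  base <- vapply(seqs, function(s)
    as.numeric(hybridizationTm(s, revComp(s), params)), numeric(1))
  ref <- unname(base) + 3.25
  cal <- calibrateTmOffset(seqs, ref, params)
  expect_equal(attr(cal, "offset"), 3.25, tolerance = 1e-9)
  expect_equal(as.numeric(hybridizationTm(seqs[1], revComp(seqs[1]), cal)),
               ref[1], tolerance = 1e-9)
  # offset shifts every reported Tm, including self-dimers
  expect_equal(as.numeric(hybridizationTm(seqs[2], seqs[2], cal)) -
                 as.numeric(hybridizationTm(seqs[2], seqs[2], params)),
               3.25, tolerance = 1e-9)
})
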