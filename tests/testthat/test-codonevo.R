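test_that("codonAlignment validates frame, gaps and internal stops", {
  expect_s4_class(codonAlignment("TTTGCTAAA", "TTCGCTAAA"), "CodonAlignment")
  expect_error(codonAlignment("TTTGCT", "TTT"), "equal length")
  expect_error(codonAlignment("TTTG", "TTCG"), "multiple of 3")
  expect_error(codonAlignment("TTTTAAAAA", "TTTGCTAAA"), "codon index 2")
})

test_that("NG86 reproduces the hand-worked example and its site counts", {
  est <- ng86(codonAlignment("TTTGCTAAA", "TTCGCTAAA"))
  ## S = (1/3 + 1 + 1/3) = 5/3 sites, Sd = 1, pS = 0.6,
  ## dS = -(3/4) log(1 - 4/3 * 0.6) = -(3/4) log(0.2)
  expect_equal(dS(est), -3 / 4 * log(0.2), tolerance = 1e-12)
  expect_equal(dN(est), 0)
  expect_identical(est@method, "NG86")
})

test_that("NG86 edge behaviour: identity, symmetry, saturation flag", {
  s <- "ATGGCTAAAGGGTTTCCC"
  expect_equal(dS(ng86(codonAlignment(s, s))), 0)
  expect_equal(dN(ng86(codonAlignment(s, s))), 0)
  a <- "TTTGCTAAAGGGACT"
  b <- "TTCGCGAAAGGTACA"
  e1 <- ng86(codonAlignment(a, b))
  e2 <- ng86(codonAlignment(b, a))
  expect_equal(dS(e1), dS(e2))
  expect_equal(dN(e1), dN(e2))
  ## saturated synonymous divergence -> correction domain flag
  sat <- ng86(codonAlignment("GCTGCTGCT", "GCAGCCGCG"))
  expect_true(is.na(dS(sat)))
})

test_that("M0 fit: zero-distance limit and parameter recovery", {
  pr0 <- simulateCodonPair(100, omega = 0.3, kappa = 2, t = 0, seed = 4)
  est0 <- m0Pairwise(pr0)
  expect_lt(dN(est0), 1e-4)
  expect_lt(dS(est0), 1e-4)

  pr <- simulateCodonPair(1000, omega = 0.3, kappa = 2, t = 0.5, seed = 42)
  est <- m0Pairwise(pr)
  expect_gt(omega(est), 0.2)
  expect_lt(omega(est), 0.4)
  expect_gt(kappa(est), 1.4)
  expect_lt(kappa(est), 2.8)
  exp <- m0ExpectedDnDs(0.3, 2, 0.5)
  expect_equal(dS(est), exp[["dS"]], tolerance = 0.15)
})

test_that("M0 likelihood is locally optimal and column-permutation invariant", {
  pr <- simulateCodonPair(300, omega = 0.5, kappa = 2, t = 0.4, seed = 7)
  est <- m0Pairwise(pr)
  cod1 <- substring(pr@seq1, seq(1, nchar(pr@seq1), 3), seq(3, nchar(pr@seq1), 3))
  cod2 <- substring(pr@seq2, seq(1, nchar(pr@seq2), 3), seq(3, nchar(pr@seq2), 3))
  counts <- TEtransfer:::.codonPairCounts(cod1, cod2)
  pi <- TEtransfer:::.f3x4(cod1, cod2)
  ll <- function(t, k, w) TEtransfer:::.m0LogLik(counts, pi, k, w, t)
  ## perturb each parameter by +/-10% in all combinations
  for (dt in c(0.9, 1.1)) for (dk in c(0.9, 1.1)) for (dw in c(0.9, 1.1)) {
    expect_lte(ll(branchLength(est) * dt, kappa(est) * dk, omega(est) * dw),
               est@logLik + 1e-6)
  }
  ## permuting codon columns leaves the likelihood unchanged
  set.seed(1)
  o <- sample(length(cod1))
  prP <- codonAlignment(paste(cod1[o], collapse = ""),
                        paste(cod2[o], collapse = ""))
  estP <- m0Pairwise(prP)
  expect_equal(estP@logLik, est@logLik, tolerance = 1e-6)
})

test_that("M0 is symmetric in sequence order", {
  pr <- simulateCodonPair(200, omega = 0.4, kappa = 2, t = 0.3, seed = 11)
  e1 <- m0Pairwise(pr)
  e2 <- m0Pairwise(codonAlignment(pr@seq2, pr@seq1))
  expect_equal(dS(e1), dS(e2), tolerance = 1e-4)
  expect_equal(dN(e1), dN(e2), tolerance = 1e-4)
})

test_that("NG86 and M0 agree on dS for moderate divergence", {
  pr <- simulateCodonPair(800, omega = 0.3, kappa = 2, t = 0.5, seed = 19)
  dsM0 <- dS(m0Pairwise(pr))
  dsNG <- dS(ng86(pr))
  expect_lt(abs(dsM0 - dsNG) / dsM0, 0.15)
})

test_that("host baseline median follows the lower-middle rule", {
  pairs <- lapply(1:4, function(i)
    simulateCodonPair(150, omega = 0.3, kappa = 2, t = 0.2 * i, seed = 100 + i))
  bl <- hostBaseline(pairs)
  expect_equal(bl$nAlignments, 4L)
  expect_equal(bl$medianDs, sort(bl$ds)[2L])   # lower of the middle pair
  one <- hostBaseline(pairs[2])
  expect_equal(one$medianDs, one$ds[1L])
  ident <- hostBaseline(list(simulateCodonPair(100, 0.3, 2, 0, seed = 1)))
  expect_lt(ident$medianDs, 1e-4)
})

test_that("dS ratio test flags published-scale contrasts and not parity", {
  mk <- function(ds) new("DnDsEstimate", method = "M0", dN = 0.1, dS = ds,
                         omega = NA_real_, kappa = 2, t = 1,
                         nCodons = 100L, logLik = 0)
  baseline <- list(ds = 1.01, medianDs = 1.01, nAlignments = 4554L)
  res <- httDsTest(list(mk(0.23), mk(0.24)), baseline)
  expect_equal(res$ratio, 1.01 / 0.235, tolerance = 1e-12)
  expect_gt(res$ratio, 4)
  expect_true(res$flagged)
  par <- httDsTest(list(mk(1.01)), baseline)
  expect_equal(par$ratio, 1)
  expect_false(par$flagged)
  zero <- httDsTest(list(mk(0)), baseline)
  expect_true(is.infinite(zero$ratio) && zero$flagged)
})

test_that("maskStopCodons drops stop-containing columns", {
  ca <- maskStopCodons("TTTTAAGCT", "TTCAAAGCT")
  expect_equal(nchar(ca@seq1), 6L)
  expect_equal(ca@seq1, "TTTGCT")
  expect_error(maskStopCodons("TAA", "TGA"), "no stop-free")
})
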