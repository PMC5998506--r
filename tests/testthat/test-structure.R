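## build an assembly with full-length elements planted at known positions
plantElements <- function(n, ltrDiv = 0, seed = 1, ltrLen = 293,
                          internalLen = 5409, gap = 20000) {
  set.seed(seed)
  ltr <- randomSeq(ltrLen)
  internal <- randomSeq(internalLen)
  pieces <- character(0)
  truth <- data.frame(start = integer(0), end = integer(0), tsd = character(0))
  pos <- 0L
  for (i in seq_len(n)) {
    bg <- randomSeq(gap)
    tsd <- randomSeq(5)
    elem <- paste0(mutateSeq(ltr, ltrDiv / 2), internal, mutateSeq(ltr, ltrDiv / 2))
    pieces <- c(pieces, bg, tsd, elem, tsd)
    s <- pos + gap + 5L + 1L
    e <- s + nchar(elem) - 1L
    truth <- rbind(truth, data.frame(start = s, end = e, tsd = tsd))
    pos <- e + 5L
  }
  pieces <- c(pieces, randomSeq(gap))
  list(assembly = DNAStringSet(c(chr1 = paste(pieces, collapse = ""))),
       truth = truth)
}

test_that("exact planted elements are recovered with their TSDs", {
  px <- plantElements(3, ltrDiv = 0, seed = 11)
  cand <- detectLTRCandidates(px$assembly)
  expect_equal(length(cand), 3L)
  expect_equal(start(cand), px$truth$start)
  expect_equal(end(cand), px$truth$end)
  expect_equal(cand$tsd, px$truth$tsd)
  expect_true(all(cand$ltrIdentity == 1))
})

test_that("solo LTRs produce no structural candidates", {
  set.seed(12)
  ltr <- randomSeq(293)
  asm <- DNAStringSet(c(chr1 = paste0(randomSeq(10000), ltr, randomSeq(10000))))
  expect_length(detectLTRCandidates(asm), 0L)
})

test_that("diverged LTR pairs are still detected near their true boundaries", {
  px <- plantElements(10, ltrDiv = 0.02, seed = 13)
  cand <- detectLTRCandidates(px$assembly)
  matched <- 0L
  for (i in seq_len(nrow(px$truth))) {
    j <- which(abs(start(cand) - px$truth$start[i]) <= 5 &
                 abs(end(cand) - px$truth$end[i]) <= 5)
    if (length(j)) matched <- matched + 1L
  }
  expect_gte(matched, 9L)
})

test_that("structural parameter ranges are validated", {
  expect_error(structuralParams(ltrLenRange = c(500, 100)), "min > max")
})

test_that("TSD lookup honors mismatch limits, edges and strand", {
  asm <- DNAStringSet(c(chr1 = paste0("AAAAAAAAAA", "GACTT", "CCCCGGGG",
                                      "GACTT", "AAAAAAAAAA")))
  iv <- GRanges("chr1", IRanges(16, 23), strand = "+")
  expect_equal(findTSD(asm, iv), "GACTT")
  ## one mismatch rejected at the default zero tolerance
  asm2 <- DNAStringSet(c(chr1 = paste0("AAAAAAAAAA", "GACTT", "CCCCGGGG",
                                       "GACTA", "AAAAAAAAAA")))
  expect_true(is.na(findTSD(asm2, iv)))
  expect_equal(findTSD(asm2, iv, structuralParams(tsdMaxMismatch = 1)), "GACTT")
  ## contig edge
  expect_warning(res <- findTSD(asm, GRanges("chr1", IRanges(2, 23))), "edge")
  expect_true(is.na(res))
  ## minus-strand interval reports the reverse complement
  ivm <- GRanges("chr1", IRanges(16, 23), strand = "-")
  expect_equal(findTSD(asm, ivm), "AAGTC")
})

test_that("TSD detection is strand-symmetric on whole assemblies", {
  px <- plantElements(2, ltrDiv = 0, seed = 14, gap = 8000)
  L <- width(px$assembly)[1]
  rc <- DNAStringSet(c(chr1 = as.character(
    Biostrings::reverseComplement(px$assembly[[1]]))))
  for (i in 1:2) {
    fwd <- findTSD(px$assembly, GRanges("chr1", IRanges(px$truth$start[i],
                                                        px$truth$end[i])))
    rev <- findTSD(rc, GRanges("chr1", IRanges(L - px$truth$end[i] + 1L,
                                               L - px$truth$start[i] + 1L)))
    expect_equal(Biostrings::reverseComplement(Biostrings::DNAString(rev)),
                 Biostrings::DNAString(fwd), ignore_attr = TRUE)
  }
})

test_that("candidate confirmation uses reciprocal overlap", {
  ann <- TEAnnotation(GRanges("c1", IRanges(c(1000, 8000), c(2000, 9000)),
    strand = "+", family = "famA", status = "full",
    internalCoverage = 0.99, has5pLTR = TRUE, has3pLTR = TRUE,
    tsd = NA_character_))
  candIdent <- GRanges("c1", IRanges(1000, 2000), ltr5Start = 1000L,
    ltr5End = 1100L, ltr3Start = 1900L, ltr3End = 2000L,
    ltrIdentity = 1, tsd = "GACTT")
  conf <- intersectCandidates(ann, candIdent)
  expect_equal(length(conf), 1L)
  expect_equal(conf$tsd, "GACTT")
  ## disjoint interval: nothing confirmed
  candOff <- GRanges("c1", IRanges(20000, 21000), ltr5Start = 1L, ltr5End = 2L,
                     ltr3Start = 3L, ltr3End = 4L, ltrIdentity = 1,
                     tsd = NA_character_)
  expect_length(intersectCandidates(ann, candOff), 0L)
  ## 60% reciprocal overlap confirms at threshold 0.5
  cand60 <- GRanges("c1", IRanges(1400, 2400), ltr5Start = 1L, ltr5End = 2L,
                    ltr3Start = 3L, ltr3End = 4L, ltrIdentity = 1,
                    tsd = NA_character_)
  expect_equal(length(intersectCandidates(ann, cand60,
                                          minReciprocalOverlap = 0.5)), 1L)
  expect_length(intersectCandidates(ann, cand60, minReciprocalOverlap = 0.7), 0L)
})

test_that("tRNA proximity distances and window flags", {
  ann <- GRanges("c1", IRanges(c(5000, 20000), c(6000, 21000)))
  trna <- GRanges("c1", IRanges(c(6001, 22002), c(6072, 22073)))
  res <- trnaProximity(ann, trna, windowBp = 1000)
  expect_equal(res$nearestTrnaDistance, c(0L, 1001L))  # abutting -> 0
  expect_equal(res$withinWindow, c(TRUE, FALSE))       # 1001 > 1000 boundary
  expect_warning(res0 <- trnaProximity(ann, GRanges()), "empty")
  expect_true(all(is.na(res0$nearestTrnaDistance)))
})

test_that("full targeting in the simulator yields 100% window membership", {
  ds <- simulateDataset(simulationConfig(seed = 15, nSpecies = 1L,
    genomeLengthBp = 150000L, nChromosomes = 1L, nTrnaGenes = 12L,
    trnaTargetingProb = 1, minInsertionSpacingBp = 3000L,
    teFamilies = list(familySpec("famA", internalLengthBp = 1200,
                                 insertionRate = 25))))
  res <- trnaProximity(ds$truth, ds$trna, windowBp = 1000)
  expect_gt(nrow(res), 3L)
  expect_true(all(res$withinWindow))
})
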