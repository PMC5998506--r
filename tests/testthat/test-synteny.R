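test_that("identical genomes yield one maximal anchor and one block", {
  s <- randomSeq(10000, seed = 1)
  q <- DNAStringSet(c(chrQ = s)); t <- DNAStringSet(c(chrT = s))
  a <- findAnchors(q, t)
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$qstart, a$qend, a$tstart, a$tend), c(1L, 10000L, 1L, 10000L))
  expect_equal(a$strand, "+")
  bl <- chainBlocks(a)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$anchoredBases, 10000L)
  ## reverse-complemented query: same span, minus strand
  qr <- DNAStringSet(c(chrQ = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  ar <- findAnchors(qr, t)
  expect_equal(nrow(ar), 1L)
  expect_equal(ar$strand, "-")
  expect_equal(c(ar$qstart, ar$qend), c(1L, 10000L))
})

test_that("anchor bases agree with a brute-force unique-substring scan", {
  set.seed(2)
  base <- randomSeq(3000)
  q <- DNAStringSet(c(c1 = mutateSeq(base, 0.03)))
  t <- DNAStringSet(c(c1 = base))
  k <- 21L
  a <- findAnchors(q, t, syntenyParams(anchorKmerLen = k))
  ## brute force: positions whose k-mer occurs exactly once in each genome
  ## (either orientation) and matches between them
  kmers <- function(s) substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  qs <- as.character(q[[1]]); ts <- as.character(t[[1]])
  qk <- kmers(qs); tk <- kmers(ts)
  qAll <- c(qk, kmers(rc(qs))); tAll <- c(tk, kmers(rc(ts)))
  qTab <- table(qAll); tTab <- table(tAll)
  good <- which(qk == tk[seq_along(qk)] & qTab[qk] == 1 & tTab[qk] == 1)
  inAnchor <- unlist(lapply(seq_len(nrow(a)), function(i)
    a$qstart[i]:(a$qend[i] - k + 1L)))
  expect_setequal(good, inAnchor)
})

test_that("block chaining applies the length filter", {
  set.seed(3)
  ## two shared segments, 1.5 kb and 3 kb, in otherwise unrelated sequence
  seg1 <- randomSeq(1500); seg2 <- randomSeq(3000)
  q <- DNAStringSet(c(c1 = paste0(randomSeq(2000), seg1, randomSeq(15000),
                                  seg2, randomSeq(2000))))
  t <- DNAStringSet(c(c1 = paste0(randomSeq(1000), seg1, randomSeq(20000),
                                  seg2, randomSeq(3000))))
  bl <- chainBlocks(findAnchors(q, t))
  expect_equal(nrow(bl), 1L)                 # the 1.5 kb segment is filtered
  expect_gte(bl$qend - bl$qstart + 1L, 2900L)
})

test_that("collinear genomes produce no breakpoints", {
  ds <- simulateDataset(simulationConfig(seed = 4, nSpecies = 2L,
    genomeLengthBp = 80000L, nChromosomes = 2L, speciesDivergence = 0.06,
    minInsertionSpacingBp = 10000L,
    teFamilies = list(familySpec("famA", internalLengthBp = 1200,
                                 insertionRate = 5))))
  bl <- chainBlocks(findAnchors(ds$assemblies$sp1, ds$assemblies$sp2))
  expect_equal(nrow(findBreakpoints(bl)), 0L)
})

test_that("a simulated reciprocal translocation is localized to its junctions", {
  cfg <- simulationConfig(seed = 5, nSpecies = 2L, genomeLengthBp = 100000L,
    nChromosomes = 2L, speciesDivergence = 0.1, minInsertionSpacingBp = 15000L,
    teFamilies = list(familySpec("famA", internalLengthBp = 3000,
                                 insertionRate = 15, divergenceScale = 0.01)),
    translocations = data.frame(chrA = "chr1", posA = 50000, chrB = "chr2",
                                posB = 60000, teAtBreakpoints = TRUE))
  ds <- simulateDataset(cfg)
  spT <- ds$translocatedSpecies
  bp <- findBreakpoints(chainBlocks(findAnchors(ds$assemblies[[spT]],
                                                ds$standardAssembly)))
  expect_equal(nrow(bp), 2L)
  expect_false(any(is.na(bp$reciprocalOf)))
  expect_true(all(bp$leftTarget != bp$rightTarget))
  ## each interval (with the association flank) contains the true junction
  for (i in seq_len(nrow(ds$truthBreakpoints))) {
    hit <- bp$qchrom == ds$truthBreakpoints$chrom[i] &
      bp$intervalStart - 1500 <= ds$truthBreakpoints$junction[i] &
      bp$intervalEnd + 1500 >= ds$truthBreakpoints$junction[i]
    expect_true(any(hit))
  }
  ann <- mergeAndClassify(findHits(ds$assemblies[[spT]], ds$library),
                          ds$canonicals)
  assoc <- associateTE(bp, ann, flankBp = 1500L)
  expect_true(all(assoc$perTranslocation$bothBreakpointsFullLength))
  expect_true(all(assoc$perTranslocation$orientationConsistent))
})

test_that("TE association is empty without nearby copies", {
  bp <- data.frame(qchrom = "chr1", intervalStart = 100L, intervalEnd = 200L,
                   leftTarget = "chr1", rightTarget = "chr2",
                   reciprocalOf = NA_integer_)
  ann <- TEAnnotation(GRanges("chr1", IRanges(50000, 56000), strand = "+",
    family = "famA", status = "full", internalCoverage = 1,
    has5pLTR = TRUE, has3pLTR = TRUE, tsd = NA_character_))
  res <- associateTE(bp, ann)
  expect_true(is.na(res$perBreakpoint$family[1]))
  expect_equal(nrow(res$perTranslocation), 0L)
})

test_that("subgenome assignment: clean, hybrid, ambiguous and unassigned", {
  set.seed(6)
  parentA <- randomSeq(20000); parentB <- mutateSeq(parentA, 0.1)
  pan <- DNAStringSet(c("A#chr1" = parentA, "B#chr1" = parentB))
  ## scaffold lifted from parent A
  scA <- DNAStringSet(c(sc1 = substr(parentA, 2000, 12000)))
  resA <- assignSubgenome(scA, pan)
  expect_equal(resA$bestParent, "A")
  expect_gt(resA$margin, 0)
  ## hybrid: half from each parent -> per-half assignment correct
  hybrid <- DNAStringSet(c(left = substr(parentA, 1, 10000),
                           right = substr(parentB, 10001, 20000)))
  resH <- assignSubgenome(hybrid, pan)
  expect_equal(resH$bestParent, c("A", "B"))
  ## equal exact halves from two unrelated parents -> ambiguous
  pX <- randomSeq(20000); pY <- randomSeq(20000)
  panU <- DNAStringSet(c("X#chr1" = pX, "Y#chr1" = pY))
  ## an N spacer keeps junction-spanning k-mers out of either tally
  half <- DNAStringSet(c(amb = paste0(substr(pX, 1, 5000),
                                      strrep("N", 25),
                                      substr(pY, 10001, 15000))))
  resM <- assignSubgenome(half, panU)
  expect_equal(resM$bestParent, "ambiguous")
  ## unrelated scaffold -> unassigned
  resU <- assignSubgenome(DNAStringSet(c(u = randomSeq(5000))), pan)
  expect_equal(resU$bestParent, "unassigned")
})
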