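makeLib <- function(internal = 600, ltr = 120, seed = 1) {
  set.seed(seed)
  DNAStringSet(c("famA#LTR" = randomSeq(ltr), "famA#internal" = randomSeq(internal)))
}

test_that("scanner finds exact planted segments on both strands only", {
  lib <- makeLib()
  bg <- randomSeq(20000, seed = 2)
  asm <- DNAStringSet(c(chr1 = paste0(substr(bg, 1, 10000),
                                      as.character(lib[["famA#internal"]]),
                                      substr(bg, 10001, 20000))))
  h <- findHits(asm, lib)
  expect_equal(length(h), 1L)
  expect_equal(start(h), 10001L)
  expect_equal(end(h), 10600L)
  expect_equal(h$identity, 100)
  expect_equal(c(h$qstart, h$qend), c(1L, 600L))
  ## reverse-complement planting maps to the minus strand, same coordinates
  asmRC <- DNAStringSet(c(chr1 = paste0(
    substr(bg, 1, 10000),
    as.character(Biostrings::reverseComplement(lib[["famA#internal"]])),
    substr(bg, 10001, 20000))))
  hRC <- findHits(asmRC, lib)
  expect_equal(as.character(strand(hRC)), "-")
  expect_equal(start(hRC), 10001L)
  ## random sequence alone yields nothing
  expect_length(findHits(DNAStringSet(c(chr1 = bg)), lib), 0L)
})

test_that("scanner input validation and masking", {
  lib <- makeLib()
  expect_error(findHits(DNAStringSet(c(chr1 = "ACGT")), DNAStringSet()),
               "empty")
  asm <- DNAStringSet(c(chr1 = paste0("ACGTRYACGT", randomSeq(100, seed = 3))))
  expect_warning(findHits(asm, lib), "masked")
})

test_that("RepeatMasker .out parsing: dialect, strand, round trip, errors", {
  out <- file.path(tempdir(), "rm.out")
  hits <- GRanges("chr2", IRanges(c(101L, 5001L), c(200L, 5400L)),
                  strand = c("+", "-"),
                  family = "Tsu4", segment = c("LTR", "internal"),
                  qstart = c(1L, 11L), qend = c(100L, 410L),
                  identity = c(98.5, 91.2))
  TEtransfer:::.writeRepeatMaskerOut(hits, out)
  back <- readRepeatMaskerOut(out)
  expect_equal(start(back), start(hits))
  expect_equal(end(back), end(hits))
  expect_equal(as.character(strand(back)), c("+", "-"))   # "C" -> minus
  expect_equal(back$family, c("Tsu4", "Tsu4"))
  expect_equal(back$segment, c("LTR", "internal"))
  expect_equal(back$qstart, hits$qstart)
  expect_equal(back$qend, hits$qend)
  expect_equal(back$identity, hits$identity, tolerance = 0.05)
  writeLines(c("h", "h", "", "1000 1.5 0.0 0.0 chr1 10"), out)
  expect_error(readRepeatMaskerOut(out), "line 4")
})

test_that("classification follows the canonical-coverage rules", {
  canon <- canonicalElement("famA", randomSeq(1240, seed = 4), 120)
  mkHits <- function(df) {
    GRanges(df$chrom, IRanges(df$start, df$end), strand = "+",
            family = "famA", segment = df$segment, qstart = df$qstart,
            qend = df$qend, identity = 99)
  }
  ## full: two LTRs + 96% internal coverage
  h <- mkHits(data.frame(chrom = "c1",
    start = c(1000, 1130, 2200), end = c(1119, 2090, 2319),
    segment = c("LTR", "internal", "LTR"),
    qstart = c(1, 10, 1), qend = c(120, 970, 120)))
  a <- mergeAndClassify(h, canon)
  expect_equal(a$status, "full")
  expect_gt(a$internalCoverage, 0.95)
  expect_true(a$has5pLTR && a$has3pLTR)
  ## truncated: one LTR, 50% coverage
  h2 <- mkHits(data.frame(chrom = "c1", start = c(1000, 1130),
    end = c(1119, 1630), segment = c("LTR", "internal"),
    qstart = c(1, 1), qend = c(120, 500)))
  expect_equal(mergeAndClassify(h2, canon)$status, "truncated")
  ## isolated LTR far from any internal hit
  h3 <- mkHits(data.frame(chrom = "c1", start = 9000, end = 9119,
    segment = "LTR", qstart = 1, qend = 120))
  a3 <- mergeAndClassify(h3, canon)
  expect_equal(a3$status, "solo")
  expect_equal(a3$internalCoverage, 0)
  ## unknown family rejected
  hBad <- h; hBad$family <- "nope"
  expect_error(mergeAndClassify(hBad, canon), "nope")
})

test_that("classification is order-insensitive, assigns every hit once, and
          does not double-count overlapping fragments", {
  canon <- canonicalElement("famA", randomSeq(1240, seed = 5), 120)
  h <- GRanges("c1", IRanges(c(1000, 1130, 1130, 2200), c(1119, 2090, 1700, 2319)),
               strand = "+", family = "famA",
               segment = c("LTR", "internal", "internal", "LTR"),
               qstart = c(1, 10, 10, 1), qend = c(120, 970, 580, 120),
               identity = 99)
  a <- mergeAndClassify(h, canon)
  expect_equal(length(a), 1L)
  ## overlapping internal fragments: coverage from the union, not the sum
  expect_lte(a$internalCoverage, 1)
  expect_equal(a$internalCoverage, 961 / 1000)
  expect_setequal(unlist(a$memberHits), 1:4)
  set.seed(6)
  aShuf <- mergeAndClassify(h[sample(4)], canon)
  expect_equal(as.data.frame(granges(aShuf)), as.data.frame(granges(a)))
  expect_equal(aShuf$status, a$status)
})

test_that("copy-number table partitions annotations and handles empties", {
  ds <- smallDataset(41)
  hits <- findHits(ds$assemblies$sp1, ds$library)
  ann <- mergeAndClassify(hits, ds$canonicals)
  tab <- copyNumberTable(list(sp1 = ann))
  expect_equal(tab$nFull + tab$nTruncated + tab$nSolo, length(ann))
  truthTab <- table(factor(ds$truth$status, c("full", "truncated", "solo")))
  expect_equal(unname(c(tab$nFull, tab$nTruncated, tab$nSolo)),
               unname(as.integer(truthTab)))
  empty <- copyNumberTable(list(s1 = ann[0]), families = "famA")
  expect_equal(empty$nFull + empty$nTruncated + empty$nSolo, 0L)
})

test_that("assembly screen applies the coverage/identity thresholds", {
  set.seed(7)
  query <- DNAStringSet(c(q = randomSeq(2000)))
  bg <- randomSeq(30000)
  plant <- function(s) DNAStringSet(c(chr1 = paste0(substr(bg, 1, 15000), s,
                                                    substr(bg, 15001, 30000))))
  full <- screenAssembly(plant(as.character(query[[1]])), query)
  expect_true(any(full$passes))
  expect_equal(max(full$queryCoverage), 1)
  expect_equal(max(full$identity), 1)
  ## only the 5' half present: coverage 0.5 fails the 80% rule
  half <- screenAssembly(plant(substr(as.character(query[[1]]), 1, 1000)), query)
  expect_false(any(half$passes))
  expect_lt(max(half$queryCoverage), 0.55)
  ## ~10% divergence still passes 80/80
  div <- screenAssembly(plant(mutateSeq(as.character(query[[1]]), 0.10)), query)
  expect_true(any(div$passes))
  best <- div[which.max(div$queryCoverage), ]
  expect_gt(best$identity, 0.85)
  expect_lt(best$identity, 0.95)
  expect_error(screenAssembly(plant("ACGT"), DNAStringSet()), "exactly one")
})

test_that("status recovery on a simulated genome meets the truth threshold", {
  ds <- smallDataset(42)
  hits <- findHits(ds$assemblies$sp1, ds$library)
  ann <- mergeAndClassify(hits, ds$canonicals)
  ov <- GenomicRanges::findOverlaps(ds$truth, granges(ann))
  expect_equal(length(unique(queryHits(ov))), length(ds$truth))
  agree <- ds$truth$status[queryHits(ov)] == ann$status[subjectHits(ov)]
  expect_gte(mean(agree), 0.95)
  ## annotations span their member hits, and hits tile nearly every base
  for (i in seq_along(ann)) {
    mh <- hits[ann$memberHits[[i]]]
    expect_true(min(start(mh)) == start(ann)[i] && max(end(mh)) == end(ann)[i])
    covered <- sum(width(GenomicRanges::reduce(granges(mh), ignore.strand = TRUE)))
    expect_gte(covered / width(ann)[i], 0.95)
  }
})
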