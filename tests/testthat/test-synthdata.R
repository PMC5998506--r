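baseConfig <- function(seed, ..., nTrnaGenes = 4L) {
  simulationConfig(seed = seed, nSpecies = 2L, genomeLengthBp = 60000L,
                   nChromosomes = 1L, minInsertionSpacingBp = 2000L,
                   nTrnaGenes = nTrnaGenes, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(baseComposition = c(0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(simulationConfig(trnaTargetingProb = 1.5), "0, 1")
  expect_error(familySpec("x", soloFormationProb = 0.8, truncationProb = 0.5),
               "0, 1")
  expect_error(familySpec("x", ltrLengthBp = 0), "ltrLengthBp")
})

test_that("no-insertion limit yields an empty truth table", {
  ds <- simulateDataset(baseConfig(1,
    teFamilies = list(familySpec("famA", insertionRate = 0))))
  expect_length(ds$truth, 0L)
})

test_that("forced state probabilities drive copy status", {
  ds <- simulateDataset(baseConfig(2, teFamilies = list(
    familySpec("famA", internalLengthBp = 1200, insertionRate = 20,
               soloFormationProb = 1, truncationProb = 0))))
  expect_gt(length(ds$truth), 0L)
  expect_true(all(ds$truth$status == "solo"))
  ## solo records contain only LTR-derived sequence (length = LTR length)
  expect_true(all(width(ds$truth) == 293L))
})

test_that("identical config and seed reproduce byte-identical output", {
  cfg <- baseConfig(3, teFamilies = list(
    familySpec("famA", internalLengthBp = 1200, insertionRate = 10)))
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  for (sp in names(d1$assemblies))
    expect_identical(as.character(d1$assemblies[[sp]]),
                     as.character(d2$assemblies[[sp]]))
  expect_identical(as.data.frame(d1$truth), as.data.frame(d2$truth))
})

test_that("TSDs are literally present in the flanks of every copy", {
  ds <- simulateDataset(baseConfig(4, teFamilies = list(
    familySpec("famA", internalLengthBp = 1200, insertionRate = 12,
               divergenceScale = 0, soloFormationProb = 0.3,
               truncationProb = 0.2))))
  tr <- ds$truth
  expect_gt(length(tr), 3L)
  for (i in seq_along(tr)) {
    seq <- ds$assemblies[[tr$species[i]]][[as.character(seqnames(tr))[i]]]
    left <- as.character(Biostrings::subseq(seq, start(tr)[i] - 5L,
                                            start(tr)[i] - 1L))
    right <- as.character(Biostrings::subseq(seq, end(tr)[i] + 1L,
                                             end(tr)[i] + 5L))
    expect_identical(left, tr$tsd[i])
    expect_identical(right, tr$tsd[i])
  }
})

test_that("tRNA targeting controls window membership in the truth table", {
  ds <- simulateDataset(baseConfig(5, trnaTargetingProb = 1, nTrnaGenes = 10L,
    teFamilies = list(familySpec("famA", internalLengthBp = 1200,
                                 insertionRate = 6))))
  expect_true(all(ds$truth$nearestTrnaDistance <= 1000))
  ds0 <- simulateDataset(baseConfig(6, trnaTargetingProb = 0,
    teFamilies = list(familySpec("famA", internalLengthBp = 1200,
                                 insertionRate = 10))))
  expect_true(all(ds0$truth$nearestTrnaDistance > 1000))
})

test_that("HTT event produces low recipient-donor element divergence", {
  cfg <- simulationConfig(seed = 8, nSpecies = 4L,
    speciesTree = "((sp1:0.15,sp2:0.15):0.15,(sp3:0.15,sp4:0.15):0.15);",
    genomeLengthBp = 60000L, nChromosomes = 1L,
    minInsertionSpacingBp = 2000L,
    teFamilies = list(familySpec("famH", internalLengthBp = 1200,
                                 insertionRate = 10, divergenceScale = 0.005,
                                 soloFormationProb = 0, truncationProb = 0,
                                 presentIn = c("sp3", "sp4"))),
    httEvent = list(donor = "sp3", recipient = "sp2", family = "famH",
                    time = 0.01, burstSize = 5L))
  ds <- simulateDataset(cfg)
  expect_true(any(ds$truth$origin == "HTT"))
  expect_true(all(ds$truth$species[ds$truth$origin == "HTT"] == "sp2"))
  getSeq <- function(i) {
    tr <- ds$truth
    as.character(Biostrings::subseq(
      ds$assemblies[[tr$species[i]]][[as.character(seqnames(tr))[i]]],
      start(tr)[i], end(tr)[i]))
  }
  rec <- which(ds$truth$species == "sp2" & ds$truth$status == "full")
  don <- which(ds$truth$species == "sp3" & ds$truth$status == "full")
  skip_if(length(rec) == 0 || length(don) == 0)
  d <- pdistanceMatrix(c(r = getSeq(rec[1]), d = getSeq(don[1])))["r", "d"]
  hostDiv <- ape::cophenetic.phylo(ds$speciesTree)["sp2", "sp3"]
  jcHostDiv <- 0.75 * (1 - exp(-4 * hostDiv / 3))   # expected observed fraction
  expect_lt(d, jcHostDiv)
})

test_that("truth record counts partition by species, family and status", {
  ds <- smallDataset(9)
  tab <- table(ds$truth$species, ds$truth$status)
  expect_equal(sum(tab), length(ds$truth))
})

test_that("codon pair simulator honors its contracts", {
  pr <- simulateCodonPair(50, omega = 0.5, kappa = 2, t = 0, seed = 1)
  expect_identical(pr@seq1, pr@seq2)
  expect_equal(nchar(pr@seq1) %% 3L, 0L)
  ## omega ~ 0 forbids amino-acid differences
  pr2 <- simulateCodonPair(400, omega = 1e-6, kappa = 2, t = 0.6, seed = 2)
  aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(pr2@seq1)))
  aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(pr2@seq2)))
  expect_identical(aa1, aa2)
  expect_error(simulateCodonPair(10, omega = -1, kappa = 2, t = 1), "omega")
  ## determinism
  a <- simulateCodonPair(100, 0.3, 2, 0.5, seed = 5)
  b <- simulateCodonPair(100, 0.3, 2, 0.5, seed = 5)
  expect_identical(a@seq2, b@seq2)
})

test_that("dataset export writes the standard formats", {
  skip_if_not_installed("rtracklayer")
  ds <- smallDataset(10)
  out <- file.path(tempdir(), "tetransfer-ds")
  files <- writeDataset(ds, out)
  expect_true(file.exists(file.path(out, "sp1.fasta")))
  expect_true(file.exists(file.path(out, "truth.bed")))
  expect_true(file.exists(file.path(out, "library.fasta")))
  ## BED round trip preserves intervals (0-based half-open on disk)
  bed <- rtracklayer::import(file.path(out, "truth.bed"))
  expect_equal(start(bed), start(ds$truth))
  expect_equal(end(bed), end(ds$truth))
  unlink(out, recursive = TRUE)
})
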