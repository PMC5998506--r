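test_that("p-distance matrix matches a brute-force double loop", {
  set.seed(5)
  rows <- vapply(1:5, function(i) randomSeq(80), "")
  rows[2] <- paste0(substr(rows[1], 1, 79), "A")   # near-duplicate pair
  names(rows) <- paste0("s", 1:5)
  d <- pdistanceMatrix(rows)
  m <- do.call(rbind, strsplit(rows, ""))
  for (i in 1:4) for (j in (i + 1):5) {
    mism <- sum(m[i, ] != m[j, ])
    expect_equal(d[i, j], mism / 80)
    expect_equal(d[i, j], d[j, i])
  }
  expect_true(all(diag(d) == 0))
  ## single differing column out of 100
  a <- randomSeq(100); b <- paste0("T", substr(a, 2, 100))
  if (substr(a, 1, 1) == "T") b <- paste0("A", substr(a, 2, 100))
  expect_equal(pdistanceMatrix(c(x = a, y = b))["x", "y"], 0.01)
  ## gap columns are pairwise-deleted; all-gap overlap errors
  expect_error(pdistanceMatrix(c(x = "AA--", y = "--AA")), "comparable")
})

test_that("neighbor joining recovers the worked additive matrix exactly", {
  d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)
  pat <- stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_true(max(abs(pat - d)) < 1e-12)      # implies AB|CD with lengths 1,2,3,4
  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  dBad <- d; dBad[1, 2] <- 99
  expect_error(neighborJoining(dBad), "symmetric")
})

test_that("neighbor joining is exact on random additive matrices", {
  for (s in 1:20) {
    n <- sample(4:12, 1)
    fix <- randomAdditiveMatrix(n, seed = 1000 + s)
    tr <- neighborJoining(fix$d)
    pat <- stats::cophenetic(tr)[rownames(fix$d), colnames(fix$d)]
    expect_lt(max(abs(pat - fix$d)), 1e-9)
    ## topology identical to the independent ape implementation
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(fix$d)))), 0)
  }
})

test_that("neighbor joining is invariant to taxon order", {
  fix <- randomAdditiveMatrix(8, seed = 77)
  tr1 <- neighborJoining(fix$d)
  o <- c(3, 1, 8, 5, 2, 7, 4, 6)
  tr2 <- neighborJoining(fix$d[o, o])
  labs <- rownames(fix$d)
  expect_lt(max(abs(stats::cophenetic(tr1)[labs, labs] -
                      stats::cophenetic(tr2)[labs, labs])), 1e-9)
})

test_that("bootstrap supports behave at the extremes and are seeded", {
  ## two tight 3-leaf clusters separated by deep divergence
  set.seed(8)
  anc <- randomSeq(1000)
  other <- mutateSeq(anc, 0.35)
  rows <- c(a1 = mutateSeq(anc, 0.01), a2 = mutateSeq(anc, 0.01),
            a3 = mutateSeq(anc, 0.01), b1 = mutateSeq(other, 0.01),
            b2 = mutateSeq(other, 0.01), b3 = mutateSeq(other, 0.01))
  tr <- bootstrapSupport(rows, nReplicates = 50, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 90)
  tr2 <- bootstrapSupport(rows, nReplicates = 50, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  tr1 <- bootstrapSupport(rows, nReplicates = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("midpoint rooting places the root on the longest path", {
  two <- list(edge = rbind(c(3L, 1L), c(3L, 2L)), edge.length = c(1, 3),
              tip.label = c("a", "b"), Nnode = 1L)
  class(two) <- "phylo"
  r2 <- midpointRoot(two)
  depths <- ape::node.depth.edgelength(r2)[1:2]
  expect_equal(unname(depths), c(2, 2))

  fix <- randomAdditiveMatrix(9, seed = 31)
  tr <- ape::unroot(fix$tree)
  mine <- midpointRoot(tr)
  ## the two deepest tips flank the root at equal depth = half the diameter
  dep <- ape::node.depth.edgelength(mine)[seq_along(mine$tip.label)]
  expect_equal(max(dep), max(fix$d) / 2, tolerance = 1e-9)
  ## agreement with the phangorn implementation
  skip_if_not_installed("phangorn")
  ref <- phangorn::midpoint(tr)
  depRef <- ape::node.depth.edgelength(ref)[seq_along(ref$tip.label)]
  expect_equal(sort(dep), sort(depRef[match(mine$tip.label, ref$tip.label)][order(match(ref$tip.label, mine$tip.label))]) * 1,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("monophyly and sister extraction agree with a bipartition scan", {
  tr <- ape::read.tree(text = "((p1:1,p2:1):1,(u1:1,c1:1):1);")
  res <- monophylyAndSister(tr, c("p1", "p2"))
  expect_true(res$isMonophyletic)
  expect_setequal(res$sisterSpecies, c("u1", "c1"))
  res2 <- monophylyAndSister(tr, c("p1", "u1"))
  expect_false(res2$isMonophyletic)
  expect_error(monophylyAndSister(tr, character(0)), "empty")
  ## random trees: monophyly equals a clade-set membership scan
  for (s in 1:5) {
    set.seed(400 + s)
    rt <- ape::rtree(12)
    tips <- sample(rt$tip.label, sample(2:5, 1))
    clades <- ape::prop.part(rt)
    labs <- attr(clades, "labels")
    inClades <- vapply(clades, function(cl) setequal(labs[cl], tips), logical(1))
    expect_equal(monophylyAndSister(rt, tips)$isMonophyletic, any(inClades))
  }
})

test_that("discordance flags a donor-clade sister but not concordant trees", {
  spTree <- ape::read.tree(text = "((par:1,cer:1):1,(uva:1,eub:1):1);")
  teTree <- ape::read.tree(
    text = "(((par_1:0.02,par_2:0.02):0.05,uva_1:0.05):0.3,(cer_1:0.1,eub_1:0.1):0.3);")
  map <- c(par_1 = "par", par_2 = "par", uva_1 = "uva", cer_1 = "cer",
           eub_1 = "eub")
  res <- discordanceTest(teTree, spTree, "par", map)
  expect_true(res$discordant)
  expect_setequal(res$observedSister, "uva")
  expect_setequal(res$expectedSister, "cer")
  ## TE tree matching the species history
  teOK <- ape::read.tree(
    text = "(((par_1:0.02,par_2:0.02):0.1,cer_1:0.1):0.3,(uva_1:0.1,eub_1:0.1):0.3);")
  expect_false(discordanceTest(teOK, spTree, "par", map)$discordant)
  expect_error(discordanceTest(teTree, spTree, "missing", map))
})

test_that("Dollo loss counts match worked cases and the DP oracle", {
  tr <- ape::read.tree(text = "((Scer:1,Spar:1):1,(Suva:1,Seub:1):1);")
  expect_equal(dolloLossCount(tr, tr$tip.label)$minLossesVertical, 0L)
  expect_equal(dolloLossCount(tr, c("Spar", "Suva"))$minLossesVertical, 2L)
  expect_equal(dolloLossCount(tr, "Spar")$minLossesVertical, 0L)
  expect_equal(dolloLossCount(tr, "Spar")$nHttEventsAlternative, 1L)
  ## oracle agreement on random trees and patterns
  for (s in 1:10) {
    set.seed(600 + s)
    rt <- ape::rtree(6)
    pres <- sample(rt$tip.label, sample(1:6, 1))
    expect_equal(dolloLossCount(rt, pres)$minLossesVertical,
                 dolloOracle(rt, pres),
                 info = paste("seed", s))
  }
})
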