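## Shared fixtures and small independent oracles for the test suite.

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## point-mutate a sequence: each site substituted with probability p
## (to a uniformly random *different* base)
mutateSeq <- function(s, p) {
  v <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

## random additive (tree-metric) distance matrix plus its generating tree
randomAdditiveMatrix <- function(nTaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(nTaxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 2)
  list(tree = tr, d = stats::cophenetic(tr))
}

## Independent Dollo oracle: dynamic program over (edge-top state, gains
## used in subtree), total gains <= 1, minimizing the number of 1->0 edges.
## Structurally different from the package's MRCA/maximal-absent-clade rule.
dolloOracle <- function(tree, presentTips) {
  nTips <- length(tree$tip.label)
  pres <- tree$tip.label %in% presentTips
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  INF <- 1e9
  ## f(v)[state+1, gains+1] = min losses in subtree of v given v's state
  f <- function(v) {
    if (v <= nTips) {
      m <- matrix(INF, 2L, 2L)
      m[pres[v] + 1L, 1L] <- 0
      return(m)
    }
    ch <- kids[[as.character(v)]]
    m <- matrix(0, 2L, 2L)      # over states x gains-used: combine children
    ## for each own state s, distribute gains among children transitions
    res <- matrix(INF, 2L, 2L)
    childTabs <- lapply(ch, f)
    for (s in 0:1) {
      ## per child: cost/gain options given parent state s
      opts <- lapply(childTabs, function(tab) {
        ## child state c, child subtree gains g
        out <- list()
        for (cs in 0:1) for (g in 0:1) {
          base <- tab[cs + 1L, g + 1L]
          if (base >= INF) next
          loss <- as.integer(s == 1L && cs == 0L)
          gain <- g + as.integer(s == 0L && cs == 1L)
          if (gain > 1L) next
          out[[length(out) + 1L]] <- c(cost = base + loss, gains = gain)
        }
        out
      })
      ## combine children under total-gain cap
      acc <- c(0, INF)          # acc[g+1] = min cost with g gains so far
      for (op in opts) {
        nxt <- c(INF, INF)
        for (g0 in 0:1) {
          if (acc[g0 + 1L] >= INF) next
          for (o in op) {
            gt <- g0 + o[["gains"]]
            if (gt > 1L) next
            nxt[gt + 1L] <- min(nxt[gt + 1L], acc[g0 + 1L] + o[["cost"]])
          }
        }
        acc <- nxt
      }
      res[s + 1L, ] <- acc
    }
    res
  }
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  tab <- f(root)
  ## root absent with the gain used below, or root present (the root's own
  ## presence is the single gain)
  min(tab[1L, 2L], tab[2L, 1L])
}

## quick dataset for annotation-oriented tests
smallDataset <- function(seed, ...) {
  simulateDataset(simulationConfig(
    seed = seed, nSpecies = 1L, genomeLengthBp = 400000L, nChromosomes = 1L,
    minInsertionSpacingBp = 15000L, nTrnaGenes = 6L,
    teFamilies = list(familySpec("famA", internalLengthBp = 3000,
                                 insertionRate = 40, divergenceScale = 0.02,
                                 soloFormationProb = 0.3,
                                 truncationProb = 0.2)), ...))
}
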