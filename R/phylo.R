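## Distance-based phylogenetics: p-distance matrices, neighbor joining with
## bootstrap support, midpoint rooting, monophyly/sister and species-tree
## discordance tests, and Dollo loss counting for presence/absence patterns.
##
## Trees are ape "phylo" objects throughout; bootstrap supports are stored
## as internal-node labels (0-100), the Newick convention.

#' @include utils.R
NULL

## Coerce alignment input (character vector of equal-length strings,
## character matrix, or DNAStringSet of equal widths) to a character matrix.
.alnMatrix <- function(alignment, mask = NULL) {
  if (is(alignment, "DNAStringSet") || is(alignment, "DNAMultipleAlignment")) {
    alignment <- as.character(alignment)
  }
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (length(unique(nchar(alignment))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    rownames(m) <- names(alignment)
    alignment <- m
  }
  if (!is.null(mask)) alignment <- alignment[, -mask, drop = FALSE]
  alignment
}

#' Pairwise p-distance matrix from a multiple alignment
#'
#' Proportion of mismatching sites per sequence pair, with pairwise deletion
#' of columns where either sequence has a gap or ambiguous base.
#'
#' @param alignment equal-length aligned sequences: named character vector,
#'   character matrix, or \code{DNAStringSet}
#' @param mask optional integer vector of alignment columns to exclude
#'   before computing distances
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames
#' @export
pdistanceMatrix <- function(alignment, mask = NULL) {
  m <- .alnMatrix(alignment, mask)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  ok <- matrix(m %in% c("A", "C", "G", "T", "a", "c", "g", "t"), nrow = n)
  m <- toupper(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp))
        stop("no comparable columns between ", labs[i], " and ", labs[j])
      d[i, j] <- d[j, i] <- mean(m[i, comp] != m[j, comp])
    }
  }
  d
}

## ---------------------------------------------------------------------------
## Neighbor joining
## ---------------------------------------------------------------------------

## Build an ape "phylo" from an adjacency list (list of data frames with
## columns node, len) rooted at rootId.  Tips are nodes with names in
## tipLabels; internal nodes are renumbered to ape's convention.
.treeFromAdjacency <- function(adj, rootId, tipIds, tipLabels) {
  nTips <- length(tipIds)
  ## DFS from root
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  stack <- list(c(rootId, NA_real_))
  seen <- rootId
  order <- c()
  edges <- list()
  walk <- function(node, from) {
    for (k in seq_len(nrow(adj[[as.character(node)]]))) {
      nb <- adj[[as.character(node)]]$node[k]
      ln <- adj[[as.character(node)]]$len[k]
      if (!is.na(from) && nb == from) next
      edges[[length(edges) + 1L]] <<- c(node, nb, ln)
      walk(nb, node)
    }
  }
  walk(rootId, NA)
  em <- do.call(rbind, edges)
  allNodes <- unique(c(em[, 1L], em[, 2L]))
  internal <- setdiff(allNodes, tipIds)
  ## root must be n+1
  internal <- c(rootId, setdiff(internal, rootId))
  map <- integer(0)
  map[as.character(tipIds)] <- seq_len(nTips)
  map[as.character(internal)] <- nTips + seq_along(internal)
  edge <- cbind(map[as.character(em[, 1L])], map[as.character(em[, 2L])])
  tr <- list(edge = unname(edge), edge.length = unname(em[, 3L]),
             tip.label = tipLabels, Nnode = length(internal))
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q-criterion.  On
#' additive distance matrices the generating topology and branch lengths are
#' recovered exactly.  Q ties are broken by the smallest (i, j) index pair;
#' negative branch-length estimates are clamped to 0 and flagged in the
#' returned tree's \code{"clamped"} attribute.
#'
#' @param d symmetric distance matrix with labelled rows/columns (at least
#'   3 taxa)
#' @return an unrooted \code{phylo} tree
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighborJoining(d)
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  nTips <- nrow(d)
  ids <- seq_len(nTips)             # active node ids
  nextId <- nTips + 1L
  adj <- list()
  addEdge <- function(a, b, len) {
    ka <- as.character(a); kb <- as.character(b)
    adj[[ka]] <<- rbind(adj[[ka]], data.frame(node = b, len = len))
    adj[[kb]] <<- rbind(adj[[kb]], data.frame(node = a, len = len))
  }
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  D <- d
  while (length(ids) > 3L) {
    N <- length(ids)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    vj <- D[i, j] - vi
    u <- nextId; nextId <- nextId + 1L
    addEdge(u, ids[i], clamp(vi))
    addEdge(u, ids[j], clamp(vj))
    newRow <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newRow[keep]),
               c(newRow[keep], 0))
    ids <- c(ids[keep], u)
  }
  ## final three-point join
  hub <- nextId
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  addEdge(hub, ids[1L], clamp(v1))
  addEdge(hub, ids[2L], clamp(v2))
  addEdge(hub, ids[3L], clamp(v3))
  tr <- .treeFromAdjacency(adj, hub, seq_len(nTips), labs)
  attr(tr, "clamped") <- clamped
  tr
}

## ---------------------------------------------------------------------------
## Bootstrap support
## ---------------------------------------------------------------------------

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and maps bipartition frequencies onto the full-data tree as
#' internal-node labels (percent of replicates).
#'
#' @param alignment aligned sequences (see \code{\link{pdistanceMatrix}})
#' @param nReplicates number of bootstrap replicates
#' @param seed integer seed; supports are deterministic given the seed
#' @param mask optional columns to exclude before resampling
#' @return the NJ tree of the full data with \code{node.label} holding
#'   supports in [0, 100] (root label empty)
#' @export
bootstrapSupport <- function(alignment, nReplicates = 100L, seed = 1L,
                             mask = NULL) {
  stopifnot(nReplicates >= 1L)
  m <- .alnMatrix(alignment, mask)
  full <- neighborJoining(pdistanceMatrix(m))
  set.seed(seed %% 2147483647)
  reps <- vector("list", nReplicates)
  for (b in seq_len(nReplicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- neighborJoining(pdistanceMatrix(m[, cols, drop = FALSE]))
  }
  cnt <- ape::prop.clades(full, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- round(100 * cnt / nReplicates)
  full$node.label <- as.character(support)
  full$node.label[1L] <- ""               # basal node: not a bipartition
  full
}

## ---------------------------------------------------------------------------
## Midpoint rooting
## ---------------------------------------------------------------------------

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.  If the
#' tree has zero total length the root is placed arbitrarily on the first
#' edge and the result carries attribute \code{"arbitraryRoot" = TRUE}.
#'
#' @param tree an unrooted (or rooted) \code{phylo} with branch lengths
#' @return a rooted \code{phylo}
#' @export
midpointRoot <- function(tree) {
  nTips <- length(tree$tip.label)
  if (nTips == 2L) {
    half <- sum(tree$edge.length) / 2
    adj <- list()
    root <- nTips + 1L
    ## direct two-leaf surgery: root half-way between the tips
    tr <- list(edge = rbind(c(3L, 1L), c(3L, 2L)),
               edge.length = c(half, sum(tree$edge.length) - half),
               tip.label = tree$tip.label, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  dn <- ape::dist.nodes(tree)
  dTips <- dn[seq_len(nTips), seq_len(nTips)]
  mx <- which(dTips == max(dTips), arr.ind = TRUE)
  mx <- mx[order(mx[, 1L], mx[, 2L]), , drop = FALSE]
  i <- mx[1L, 1L]; j <- mx[1L, 2L]
  total <- dTips[i, j]
  arbitrary <- FALSE
  if (total <= 0) {
    warning("tree has zero length; root placement is arbitrary")
    arbitrary <- TRUE
  }
  path <- ape::nodepath(tree, i, j)
  half <- total / 2
  ## walk the path accumulating distance until the midpoint edge
  acc <- 0
  edgeIdx <- NA_integer_
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    len <- dn[a, b]
    if (acc + len >= half - 1e-12) {
      edgeIdx <- k; break
    }
    acc <- acc + len
  }
  a <- path[edgeIdx]; b <- path[edgeIdx + 1L]
  xa <- half - acc                        # distance from a to root point
  xb <- dn[a, b] - xa
  ## adjacency of the whole tree with a new root node on edge (a, b)
  nNodes <- nTips + tree$Nnode
  rootId <- nNodes + 1L
  adj <- list()
  addEdge <- function(p, q, len) {
    kp <- as.character(p); kq <- as.character(q)
    adj[[kp]] <<- rbind(adj[[kp]], data.frame(node = q, len = len))
    adj[[kq]] <<- rbind(adj[[kq]], data.frame(node = p, len = len))
  }
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; q <- tree$edge[e, 2L]
    if ((p == a && q == b) || (p == b && q == a)) next
    addEdge(p, q, tree$edge.length[e])
  }
  addEdge(rootId, a, max(xa, 0))
  addEdge(rootId, b, max(xb, 0))
  out <- .treeFromAdjacency(adj, rootId, seq_len(nTips), tree$tip.label)
  out <- .dropDegreeTwoRoot(out)
  attr(out, "arbitraryRoot") <- arbitrary
  out
}

## The old basal trichotomy node can be left with degree 2 after rerooting;
## ape handles such nodes poorly, so merge its two incident edges.
.dropDegreeTwoRoot <- function(tree) {
  repeat {
    nTips <- length(tree$tip.label)
    tab <- tabulate(tree$edge, nbins = nTips + tree$Nnode)
    deg2 <- which(tab == 2L & seq_along(tab) > nTips)
    root <- tree$edge[1L, 1L]
    deg2 <- setdiff(deg2, root)
    if (!length(deg2)) return(tree)
    v <- deg2[1L]
    inE <- which(tree$edge[, 2L] == v)
    outE <- which(tree$edge[, 1L] == v)
    tree$edge[inE, 2L] <- tree$edge[outE, 2L]
    tree$edge.length[inE] <- tree$edge.length[inE] + tree$edge.length[outE]
    tree$edge <- tree$edge[-outE, , drop = FALSE]
    tree$edge.length <- tree$edge.length[-outE]
    ## renumber internal nodes to stay contiguous
    old <- sort(unique(as.vector(tree$edge)))
    oldInt <- old[old > nTips]
    map <- integer(max(old))
    map[seq_len(nTips)] <- seq_len(nTips)
    map[oldInt] <- nTips + seq_along(oldInt)
    tree$edge[] <- map[tree$edge]
    tree$Nnode <- length(oldInt)
  }
}

## ---------------------------------------------------------------------------
## Monophyly, discordance, Dollo
## ---------------------------------------------------------------------------

.tipDescendants <- function(tree, node) {
  nTips <- length(tree$tip.label)
  if (node <= nTips) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    out <- c(out, kids[kids <= nTips])
    stack <- c(stack, kids[kids > nTips])
  }
  sort(out)
}

#' Monophyly test and sister-group extraction
#'
#' Tests whether a set of leaves forms a clade in a rooted tree, and
#' reports the species found in the sister group of that set's most recent
#' common ancestor.
#'
#' @param tree rooted \code{phylo}
#' @param focalLeaves character vector of tip labels
#' @param leafToSpecies named character vector mapping every tip label to a
#'   species; defaults to the identity (tips are species)
#' @return list with \code{isMonophyletic} (logical) and \code{sisterSpecies}
#'   (character; empty when the focal MRCA is the root)
#' @export
monophylyAndSister <- function(tree, focalLeaves,
                               leafToSpecies = setNames(tree$tip.label,
                                                        tree$tip.label)) {
  if (!length(focalLeaves)) stop("focal leaf set is empty")
  stopifnot(all(focalLeaves %in% tree$tip.label))
  nTips <- length(tree$tip.label)
  focalIdx <- match(focalLeaves, tree$tip.label)
  mrca <- if (length(focalIdx) == 1L) focalIdx else ape::getMRCA(tree, focalIdx)
  desc <- .tipDescendants(tree, mrca)
  mono <- setequal(desc, focalIdx)
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  sisterSpecies <- character(0)
  if (mrca != root) {
    parent <- tree$edge[tree$edge[, 2L] == mrca, 1L]
    sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], mrca)
    sisTips <- unlist(lapply(sibs, .tipDescendants, tree = tree))
    sisterSpecies <- sort(unique(unname(leafToSpecies[tree$tip.label[sisTips]])))
  }
  list(isMonophyletic = mono, sisterSpecies = sisterSpecies)
}

#' Species-tree discordance test
#'
#' Compares the sister group of a focal species set in the element (TE)
#' tree with its sister group in the species tree.  The element tree is
#' discordant when the observed sister-species set is disjoint from the
#' expected one: the element's nearest relatives are not where the species
#' history puts them, the classic phylogenetic signature of horizontal
#' transfer.
#'
#' @param teTree rooted \code{phylo} of element copies
#' @param speciesTree rooted \code{phylo} of the species
#' @param focalSpecies character vector of focal species names
#' @param leafToSpecies named character vector mapping TE-tree tips to
#'   species
#' @param pruneToObserved when TRUE (default), the expected sister is read
#'   from the species tree pruned to the species actually represented in
#'   the element tree, so that species without sampled copies cannot
#'   create spurious discordance
#' @return list with \code{discordant}, \code{observedSister},
#'   \code{expectedSister}
#' @export
discordanceTest <- function(teTree, speciesTree, focalSpecies, leafToSpecies,
                            pruneToObserved = TRUE) {
  stopifnot(all(focalSpecies %in% speciesTree$tip.label))
  focalLeaves <- names(leafToSpecies)[leafToSpecies %in% focalSpecies]
  if (!length(focalLeaves))
    stop("no TE-tree leaves map to the focal species: ",
         paste(focalSpecies, collapse = ", "))
  obs <- monophylyAndSister(teTree, focalLeaves, leafToSpecies)
  observedSister <- setdiff(obs$sisterSpecies, focalSpecies)
  spTree <- speciesTree
  if (pruneToObserved) {
    present <- intersect(speciesTree$tip.label,
                         unique(c(unname(leafToSpecies), focalSpecies)))
    if (length(present) >= 3L && length(present) < length(speciesTree$tip.label))
      spTree <- ape::keep.tip(speciesTree, present)
  }
  exp <- monophylyAndSister(spTree, intersect(focalSpecies, spTree$tip.label))
  expectedSister <- setdiff(exp$sisterSpecies, focalSpecies)
  list(discordant = length(observedSister) > 0 && length(expectedSister) > 0 &&
         !any(observedSister %in% expectedSister),
       observedSister = observedSister, expectedSister = expectedSister)
}

#' Dollo loss count for a presence/absence pattern
#'
#' Under Dollo parsimony the family is gained once, at the most recent
#' common ancestor of the species that carry it, and only lost thereafter.
#' The minimum number of losses is the number of maximal carrier-free
#' subtrees below that ancestor.  The competing explanation, a single
#' horizontal transfer into the recipient lineage, always costs one event;
#' both counts are reported so the explanations can be compared.
#'
#' @param speciesTree rooted \code{phylo}
#' @param presentSpecies character vector of species carrying the family
#' @return list with \code{minLossesVertical} and
#'   \code{nHttEventsAlternative} (always 1)
#' @export
dolloLossCount <- function(speciesTree, presentSpecies) {
  if (!length(presentSpecies)) stop("at least one species must be present")
  stopifnot(all(presentSpecies %in% speciesTree$tip.label))
  nTips <- length(speciesTree$tip.label)
  presIdx <- match(presentSpecies, speciesTree$tip.label)
  gain <- if (length(presIdx) == 1L) presIdx else ape::getMRCA(speciesTree, presIdx)
  losses <- 0L
  if (gain > nTips) {
    hasPresent <- function(node) any(.tipDescendants(speciesTree, node) %in% presIdx)
    stack <- gain
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      kids <- speciesTree$edge[speciesTree$edge[, 1L] == cur, 2L]
      for (k in kids) {
        if (hasPresent(k)) {
          if (k > nTips) stack <- c(stack, k)
        } else {
          losses <- losses + 1L            # maximal carrier-free subtree
        }
      }
    }
  }
  list(minLossesVertical = losses, nHttEventsAlternative = 1L)
}
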