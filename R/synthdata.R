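## Genome and TE simulator with ground truth.
##
## Generates per-species assemblies carrying LTR-retrotransposon copies in
## three states (full-length, truncated, solo LTR) with 5-bp target site
## duplications and tRNA-adjacent insertion preference, an optional
## horizontal transfer event with a post-transfer burst, host CDS pairs for
## the synonymous-divergence baseline, and optional reciprocal
## translocations with TE copies at the breakpoints.  Every TE copy is
## recorded in a truth table so downstream stages can be scored.

#' @include AllClasses.R codonevo.R
NULL

## Evolve a coded sequence by d substitutions/site while keeping an in-frame
## region free of stop codons: codons that mutate into stops revert.
.evolveCodesNoStop <- function(codes, d) {
  out <- .evolveCodes(codes, d)
  nCod <- length(out) %/% 3L
  if (nCod == 0L) return(out)
  idx <- matrix(seq_len(nCod * 3L), nrow = 3L)
  cods <- paste0(DNA_BASES[out[idx[1L, ]] + 1L], DNA_BASES[out[idx[2L, ]] + 1L],
                 DNA_BASES[out[idx[3L, ]] + 1L])
  bad <- which(.codonData$gc[cods] == "*")
  for (b in bad) out[idx[, b]] <- codes[idx[, b]]
  out
}

## Random in-frame stop-free coding sequence of n codons, as codes.
.randomCodingCodes <- function(nCodons) {
  cods <- sample(.codonData$sense, nCodons, replace = TRUE)
  .baseCodes(strsplit(paste(cods, collapse = ""), "")[[1L]])
}

## Evolve a set of sequences down a species tree; returns a list of coded
## sequences per tip label.  `rate` scales branch lengths.
.evolveAlongTree <- function(codes, tree, rate = 1) {
  nTips <- length(tree$tip.label)
  root <- tree$edge[1L, 1L]
  states <- list()
  states[[as.character(root)]] <- codes
  out <- list()
  ## edges in cladewise order: parents always visited before children
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    evolved <- .evolveCodes(states[[as.character(p)]],
                            tree$edge.length[e] * rate)
    if (ch <= nTips) {
      out[[tree$tip.label[ch]]] <- evolved
    } else {
      states[[as.character(ch)]] <- evolved
    }
  }
  out
}

.scaledCoalTree <- function(n, height) {
  tr <- ape::rcoal(n, tip.label = paste0("sp", seq_len(n)))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height / depth
  tr
}

## ---------------------------------------------------------------------------
## Insertion-site sampling
## ---------------------------------------------------------------------------

## Sample insertion sites on one chromosome honoring the tRNA-targeting
## probability, a minimum spacing between sites, and a guard band keeping
## untargeted sites > 1 kb away from every tRNA so the truth window flag is
## unambiguous.
.sampleSites <- function(nSites, chromLen, trnaStarts, trnaEnds, targetProb,
                         minSpacing, window = 1000L, reserved = integer(0)) {
  sites <- as.integer(reserved); targeted <- rep(FALSE, length(reserved))
  guard <- window + 200L
  edge <- 500L
  for (k in seq_len(nSites)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      tgt <- runif(1) < targetProb && length(trnaStarts) > 0L
      if (tgt) {
        ti <- sample.int(length(trnaStarts), 1L)
        off <- sample(20:150, 1L)
        s <- if (runif(1) < 0.5) trnaStarts[ti] - off else trnaEnds[ti] + off
      } else {
        s <- sample.int(chromLen - 2L * edge, 1L) + edge
        if (length(trnaStarts) &&
            min(pmax(trnaStarts - s, s - trnaEnds, 0L)) <= guard) next
      }
      if (s < edge || s > chromLen - edge) next
      if (length(sites) && min(abs(sites - s)) < minSpacing) next
      sites <- c(sites, as.integer(s)); targeted <- c(targeted, tgt)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("insertion-site placement failed: retries exhausted ",
           "(chromosome too crowded for the requested spacing)")
  }
  keep <- seq_along(sites) > length(reserved)
  list(sites = sites[keep], targeted = targeted[keep])
}

## ---------------------------------------------------------------------------
## Main generator
## ---------------------------------------------------------------------------

#' Simulate a multi-species dataset with TE ground truth
#'
#' Generates everything the analysis pipeline consumes: per-species genome
#' assemblies with planted TE copies (full-length, truncated, solo LTR; TSDs
#' literally present in the flanks), a truth table, tRNA gene annotations,
#' a TE reference library with LTR/internal segments, host CDS pairs, and
#' the species tree.  With an HTT event configured, the recipient lineage's
#' copies of the transferred family derive from the donor lineage at the
#' transfer time, so their divergence to donor copies is far below the
#' host divergence between the clades.  Reciprocal translocations, applied
#' after TE insertion, can be requested with full-length copies at the
#' breakpoints.
#'
#' All output is a deterministic function of \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a list with elements \code{assemblies} (named list of
#'   \code{DNAStringSet}), \code{truth} (\code{GRanges} with columns
#'   species, family, status, tsd, nearestTrnaDistance, targeted, origin),
#'   \code{trna} (\code{GRanges} with a species column), \code{library}
#'   (\code{DNAStringSet} named "family#LTR"/"family#internal"),
#'   \code{canonicals} (list of \linkS4class{CanonicalElement}),
#'   \code{cdsPairs} (list of \linkS4class{CodonAlignment}),
#'   \code{cdsSpecies} (the two species the CDS pairs compare),
#'   \code{speciesTree} (\code{phylo} or NULL), \code{standardAssembly}
#'   (pre-translocation first-species assembly, or NULL) and
#'   \code{truthBreakpoints} (data.frame of junctions in derived
#'   coordinates)
#' @examples
#' cfg <- simulationConfig(seed = 1, nSpecies = 4, genomeLengthBp = 60000,
#'                         nChromosomes = 1,
#'                         teFamilies = list(familySpec("famA",
#'                           internalLengthBp = 1200, insertionRate = 3)))
#' ds <- simulateDataset(cfg)
#' table(ds$truth$species, ds$truth$status)
#' @export
simulateDataset <- function(config) {
  validObject(config)
  set.seed(config@seed %% 2147483647)
  nSp <- config@nSpecies

  ## species history
  if (nSp > 1L) {
    tree <- if (identical(config@speciesTree, "random")) {
      .scaledCoalTree(nSp, config@speciesDivergence)
    } else {
      ape::read.tree(text = config@speciesTree)
    }
    tree <- ape::reorder.phylo(tree, "cladewise")
    species <- tree$tip.label
  } else {
    tree <- NULL
    species <- "sp1"
  }

  ## family canonicals and the reference library
  canonicals <- list(); lib <- character(0)
  for (fam in config@teFamilies) {
    ltr <- .randomCodes(fam@ltrLengthBp, config@baseComposition)
    internal <- .randomCodingCodes(fam@internalLengthBp %/% 3L)
    canon <- c(ltr, internal, ltr)
    canonicals[[fam@name]] <- canonicalElement(
      fam@name, .codesToSeq(canon), fam@ltrLengthBp)
    lib[paste0(fam@name, "#LTR")] <- .codesToSeq(ltr)
    lib[paste0(fam@name, "#internal")] <- .codesToSeq(internal)
  }
  library <- DNAStringSet(lib)

  ## per-species family masters (vertical evolution along the tree)
  masters <- list()
  for (fam in config@teFamilies) {
    canonCodes <- .seqToCodes(as.character(canonicalSequence(canonicals[[fam@name]])))
    masters[[fam@name]] <- if (is.null(tree)) {
      setNames(list(canonCodes), species)
    } else {
      .evolveAlongTree(canonCodes, tree)
    }
  }
  ## horizontal transfer: recipient master re-derived from the donor lineage
  htt <- config@httEvent
  if (!is.null(htt)) {
    masters[[htt$family]][[htt$recipient]] <-
      .evolveCodes(masters[[htt$family]][[htt$donor]], 2 * htt$time)
  }

  ## host genome backgrounds
  chromNames <- paste0("chr", seq_len(config@nChromosomes))
  ancestral <- lapply(chromNames, function(ch)
    .randomCodes(config@genomeLengthBp, config@baseComposition))
  names(ancestral) <- chromNames
  genomes <- list()
  for (ch in chromNames) {
    if (is.null(tree)) {
      genomes[[ch]] <- setNames(list(ancestral[[ch]]), species)
    } else {
      genomes[[ch]] <- .evolveAlongTree(ancestral[[ch]], tree)
    }
  }

  rootToTip <- if (is.null(tree)) {
    setNames(config@speciesDivergence, species)
  } else {
    setNames(ape::node.depth.edgelength(tree)[seq_len(nSp)], species)
  }

  ## plan insertions per species
  assemblies <- list()
  truthRows <- list()
  trnaRows <- list()
  siteShiftsBySpecies <- list()   # for translocation coordinate mapping
  trl <- config@translocations
  wantBpTE <- nrow(trl) > 0 && any(trl$teAtBreakpoints)

  for (sp in species) {
    ## tRNA genes per chromosome
    trnaBySite <- list()
    for (ch in chromNames) {
      pos <- integer(0)
      for (g in seq_len(config@nTrnaGenes)) {
        for (try in seq_len(2000L)) {
          p <- sample.int(config@genomeLengthBp - 4000L, 1L) + 2000L
          if (!length(pos) || min(abs(pos - p)) >= 2000L) { pos <- c(pos, p); break }
          if (try == 2000L) stop("tRNA placement failed: retries exhausted")
        }
      }
      pos <- sort(pos)
      trnaBySite[[ch]] <- data.frame(start = pos, end = pos + 71L)
    }

    ## insertion counts per family
    plan <- list()
    for (fam in config@teFamilies) {
      active <- identical(fam@presentIn, "all") || sp %in% fam@presentIn
      nIns <- if (active) rpois(1L, fam@insertionRate * rootToTip[[sp]]) else 0L
      if (!is.null(htt) && htt$family == fam@name) {
        if (sp == htt$recipient) nIns <- as.integer(htt$burstSize)
        else if (!active && !identical(fam@presentIn, "all")) nIns <- nIns
      }
      if (nIns > 0L)
        plan[[fam@name]] <- nIns
    }

    ## breakpoint-requested full-length copies (first species only)
    bpHere <- sp == species[1L] && wantBpTE
    bpFam <- if (length(config@teFamilies)) config@teFamilies[[1L]]@name else NULL

    ## spread insertions over chromosomes, then sample sites
    events <- list()
    for (famName in names(plan)) {
      n <- plan[[famName]]
      chs <- sample(chromNames, n, replace = TRUE)
      for (ch in chromNames) {
        k <- sum(chs == ch)
        if (k > 0L) events[[length(events) + 1L]] <-
            data.frame(chrom = ch, family = famName, n = k)
      }
    }

    ## forced breakpoint insertions: full-length copies whose 3' end is cut;
    ## their sites are reserved before ordinary site sampling so random
    ## insertions keep clear of the breakpoint neighbourhoods
    forced <- NULL
    if (bpHere && !is.null(bpFam)) {
      forced <- do.call(rbind, lapply(seq_len(nrow(trl)), function(i) {
        if (!trl$teAtBreakpoints[i]) return(NULL)
        data.frame(chrom = c(trl$chrA[i], trl$chrB[i]),
                   site = c(trl$posA[i], trl$posB[i]), trlIdx = i)
      }))
    }

    perChromSites <- list()
    for (ch in chromNames) {
      needed <- sum(vapply(events, function(e)
        if (e$chrom == ch) e$n else 0L, numeric(1)))
      tr <- trnaBySite[[ch]]
      reserved <- if (!is.null(forced)) forced$site[forced$chrom == ch]
                  else integer(0)
      ss <- .sampleSites(needed, config@genomeLengthBp, tr$start, tr$end,
                         config@trnaTargetingProb, config@minInsertionSpacingBp,
                         reserved = reserved)
      perChromSites[[ch]] <- ss
    }

    ## build per-chromosome insertion tables
    spTruth <- list()
    newChrom <- list()
    trnaFinal <- list()
    siteShifts <- list()      # for translocation coordinate mapping
    for (ch in chromNames) {
      ss <- perChromSites[[ch]]
      famOfSite <- character(0)
      for (e in events) if (e$chrom == ch)
        famOfSite <- c(famOfSite, rep(e$family, e$n))
      tab <- if (length(ss$sites)) {
        data.frame(site = ss$sites, targeted = ss$targeted, family = famOfSite,
                   forcedFull = FALSE, trlIdx = NA_integer_)
      } else {
        data.frame(site = integer(0), targeted = logical(0),
                   family = character(0), forcedFull = logical(0),
                   trlIdx = integer(0))
      }
      if (!is.null(forced)) {
        f <- forced[forced$chrom == ch, , drop = FALSE]
        if (nrow(f)) {
          ## forced copies only need local clearance (no other copy within
          ## the breakpoint neighbourhood), not the global spacing
          if (length(tab$site) && any(outer(tab$site, f$site, function(a, b)
            abs(a - b) < 5000L)))
            stop("translocation position conflicts with an existing TE copy: ",
                 "placement error, retries exhausted")
          tab <- rbind(tab, data.frame(site = f$site, targeted = FALSE,
                                       family = bpFam, forcedFull = TRUE,
                                       trlIdx = f$trlIdx))
        }
      }
      tab <- tab[order(tab$site), , drop = FALSE]

      host <- genomes[[ch]][[sp]]
      pieces <- list(); cursor <- 1L; shift <- 0L
      rows <- list()
      shifts <- data.frame(site = tab$site,
                           shiftAfter = rep(NA_integer_, nrow(tab)),
                           elemEnd = rep(NA_integer_, nrow(tab)))
      for (r in seq_len(nrow(tab))) {
        fam <- config@teFamilies[[
          which(vapply(config@teFamilies, function(f) f@name, "") == tab$family[r])]]
        master <- masters[[fam@name]][[sp]]
        ltrLen <- fam@ltrLengthBp
        intLen <- fam@internalLengthBp
        status <- if (tab$forcedFull[r]) "full" else {
          u <- runif(1)
          if (u < fam@soloFormationProb) "solo"
          else if (u < fam@soloFormationProb + fam@truncationProb) "truncated"
          else "full"
        }
        ## breakpoint-requested copies are fresh (identical) insertions, so
        ## they stay anchor-free in whole-genome comparisons like any
        ## recently proliferated repeat
        copyDiv <- if (tab$forcedFull[r]) 0 else runif(1, 0, 2 * fam@divergenceScale)
        origin <- if (!is.null(htt) && htt$family == fam@name &&
                      sp == htt$recipient) "HTT" else "vertical"
        body <- switch(status,
          full = .evolveCodes(master, copyDiv),
          solo = .evolveCodes(master[seq_len(ltrLen)], copyDiv),
          truncated = {
            f <- runif(1, 0.3, 0.8)
            keepLen <- as.integer(round(f * intLen))
            idx <- c((ltrLen + intLen - keepLen + 1L):(ltrLen + intLen),
                     (ltrLen + intLen + 1L):(2L * ltrLen + intLen))
            .evolveCodes(master[idx], copyDiv)
          })
        s <- tab$site[r]
        tsdLen <- fam@tsdLengthBp
        tsd <- host[(s - tsdLen + 1L):s]
        pieces[[length(pieces) + 1L]] <- host[cursor:s]
        pieces[[length(pieces) + 1L]] <- body
        pieces[[length(pieces) + 1L]] <- tsd
        cursor <- s + 1L
        elemStart <- s + shift + 1L
        elemEnd <- s + shift + length(body)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = elemStart, end = elemEnd, strand = "+",
          species = sp, family = fam@name, status = status,
          tsd = .codesToSeq(tsd), targeted = tab$targeted[r],
          origin = origin, copyDiv = copyDiv, trlIdx = tab$trlIdx[r])
        shifts$elemEnd[r] <- elemEnd
        shift <- shift + length(body) + tsdLen
        shifts$shiftAfter[r] <- shift
      }
      pieces[[length(pieces) + 1L]] <- host[cursor:length(host)]
      newChrom[[ch]] <- unlist(pieces, use.names = FALSE)
      spTruth[[ch]] <- if (length(rows)) do.call(rbind, rows) else NULL
      siteShifts[[ch]] <- shifts

      ## tRNA final coordinates
      tr <- trnaBySite[[ch]]
      if (nrow(tr)) {
        shiftOf <- function(p) {
          if (!nrow(tab)) return(0L)
          done <- which(tab$site < p)
          if (!length(done)) 0L else siteShifts[[ch]]$shiftAfter[max(done)]
        }
        tr$start <- tr$start + vapply(tr$start, shiftOf, integer(1))
        tr$end <- tr$end + vapply(tr$end - 71L, shiftOf, integer(1)) + 0L
        trnaFinal[[ch]] <- data.frame(chrom = ch, start = tr$start,
                                      end = tr$end, species = sp)
      }
    }

    assemblies[[sp]] <- DNAStringSet(vapply(newChrom, .codesToSeq, ""))
    names(assemblies[[sp]]) <- chromNames
    spTruth <- do.call(rbind, Filter(Negate(is.null), spTruth))
    truthRows[[sp]] <- spTruth
    trnaRows[[sp]] <- do.call(rbind, trnaFinal)
    siteShiftsBySpecies[[sp]] <- siteShifts
  }

  ## reciprocal translocations on species 1
  standardAssembly <- NULL
  truthBreakpoints <- data.frame()
  if (nrow(trl)) {
    sp1 <- species[1L]
    standardAssembly <- assemblies[[sp1]]
    siteShifts <- siteShiftsBySpecies[[sp1]]
    asm <- as.list(assemblies[[sp1]])
    t1 <- truthRows[[sp1]]
    bps <- list()
    for (i in seq_len(nrow(trl))) {
      chA <- trl$chrA[i]; chB <- trl$chrB[i]
      ## cut coordinates in current (post-insertion) coordinates
      cutOf <- function(ch, pos) {
        sh <- siteShifts[[ch]]
        if (trl$teAtBreakpoints[i]) {
          idx <- which(!is.na(t1$trlIdx) & t1$trlIdx == i & t1$chrom == ch)
          if (length(idx)) return(t1$end[idx[1L]] + 5L)  # just past TSD
        }
        done <- which(sh$site < pos)
        shift <- if (!length(done)) 0L else sh$shiftAfter[max(done)]
        cut <- pos + shift
        inside <- !is.na(t1$chrom) & t1$chrom == ch & t1$start <= cut & t1$end >= cut
        if (any(inside & is.na(t1$trlIdx)))
          stop("translocation position lies inside a TE copy: placement error, ",
               "retries exhausted")
        ## keep plain (non-TE-mediated) junctions well clear of TE copies so
        ## breakpoint-TE association has an unambiguous truth value
        onCh <- !is.na(t1$chrom) & t1$chrom == ch
        clearance <- 3000L
        tries <- 0L
        while (any(onCh & t1$start - clearance <= cut &
                     t1$end + clearance >= cut)) {
          cut <- cut + 500L
          tries <- tries + 1L
          if (tries > 50L)
            stop("translocation position cannot be placed clear of TE ",
                 "copies: placement error, retries exhausted")
        }
        cut
      }
      cutA <- cutOf(chA, trl$posA[i]); cutB <- cutOf(chB, trl$posB[i])
      sA <- .seqToCodes(as.character(asm[[chA]]))
      sB <- .seqToCodes(as.character(asm[[chB]]))
      newA <- c(sA[1:cutA], sB[(cutB + 1L):length(sB)])
      newB <- c(sB[1:cutB], sA[(cutA + 1L):length(sA)])
      asm[[chA]] <- DNAString(.codesToSeq(newA))
      asm[[chB]] <- DNAString(.codesToSeq(newB))
      ## remap species-1 truth coordinates across the exchange
      onA <- !is.na(t1$chrom) & t1$chrom == chA & t1$start > cutA
      onB <- !is.na(t1$chrom) & t1$chrom == chB & t1$start > cutB
      newStartA <- t1$start[onB] - cutB + cutA
      t1$end[onB] <- t1$end[onB] - cutB + cutA
      t1$end[onA] <- t1$end[onA] - cutA + cutB
      t1$start[onB] <- newStartA
      t1$start[onA] <- t1$start[onA] - cutA + cutB
      t1$chrom[onA] <- chB; t1$chrom[onB] <- chA
      bps[[length(bps) + 1L]] <- data.frame(
        translocation = i, chrom = c(chA, chB), junction = c(cutA, cutB),
        teAtBreakpoints = trl$teAtBreakpoints[i])
    }
    assemblies[[sp1]] <- DNAStringSet(vapply(asm, as.character, ""))
    names(assemblies[[sp1]]) <- chromNames
    truthRows[[sp1]] <- t1
    truthBreakpoints <- do.call(rbind, bps)
  }

  ## assemble truth GRanges and tRNA GRanges
  truthDf <- do.call(rbind, Filter(Negate(is.null), truthRows))
  trnaDf <- do.call(rbind, Filter(Negate(is.null), trnaRows))
  if (is.null(truthDf) || !nrow(truthDf)) {
    truth <- GenomicRanges::GRanges()
  } else {
    truth <- GenomicRanges::GRanges(
      seqnames = truthDf$chrom,
      ranges = IRanges::IRanges(truthDf$start, truthDf$end),
      strand = truthDf$strand, species = truthDf$species,
      family = truthDf$family, status = truthDf$status, tsd = truthDf$tsd,
      targeted = truthDf$targeted, origin = truthDf$origin,
      copyDiv = truthDf$copyDiv)
    ## nearest tRNA distance per copy (same species)
    dist <- rep(NA_integer_, length(truth))
    for (sp in species) {
      sel <- which(truthDf$species == sp)
      tr <- trnaDf[trnaDf$species == sp, , drop = FALSE]
      if (!length(sel) || is.null(tr) || !nrow(tr)) next
      for (k in sel) {
        same <- tr$chrom == truthDf$chrom[k]
        if (!any(same)) next
        gaps <- pmax(tr$start[same] - truthDf$end[k] - 1L,
                     truthDf$start[k] - tr$end[same] - 1L, 0L)
        dist[k] <- min(gaps)
      }
    }
    truth$nearestTrnaDistance <- dist
  }
  trna <- if (is.null(trnaDf) || !nrow(trnaDf)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(seqnames = trnaDf$chrom,
                           ranges = IRanges::IRanges(trnaDf$start, trnaDf$end),
                           strand = "+", species = trnaDf$species)

  ## host CDS pairs between the most informative species pair
  cdsPairs <- list()
  cdsSpecies <- character(0)
  if (config@nCdsPairs > 0L) {
    if (!is.null(htt)) {
      cdsSpecies <- c(htt$donor, htt$recipient)
    } else if (!is.null(tree)) {
      D <- ape::cophenetic.phylo(tree)
      mx <- which(D == max(D), arr.ind = TRUE)[1L, ]
      cdsSpecies <- c(rownames(D)[mx[1L]], colnames(D)[mx[2L]])
    } else {
      cdsSpecies <- c(species[1L], species[1L])
    }
    d <- if (!is.null(tree))
      ape::cophenetic.phylo(tree)[cdsSpecies[1L], cdsSpecies[2L]]
    else config@speciesDivergence
    for (k in seq_len(config@nCdsPairs)) {
      anc <- .randomCodingCodes(config@cdsLengthCodons)
      a <- .evolveCodesNoStop(anc, d / 2)
      b <- .evolveCodesNoStop(anc, d / 2)
      cdsPairs[[k]] <- codonAlignment(.codesToSeq(a), .codesToSeq(b),
                                      labels = cdsSpecies)
    }
  }

  list(assemblies = assemblies, truth = truth, trna = trna,
       library = library, canonicals = canonicals, cdsPairs = cdsPairs,
       cdsSpecies = cdsSpecies, speciesTree = tree,
       standardAssembly = standardAssembly,
       translocatedSpecies = if (nrow(trl)) species[1L] else NA_character_,
       truthBreakpoints = truthBreakpoints, config = config)
}

## ---------------------------------------------------------------------------
## Codon-pair simulator (GY94/M0)
## ---------------------------------------------------------------------------

#' Simulate an in-frame coding pair under the M0 codon model
#'
#' Draws an ancestral sequence from the stationary codon distribution and
#' evolves one copy for divergence t (substitutions per codon) under the
#' Goldman-Yang one-ratio model; by reversibility the resulting pair is
#' equivalent to two lineages separated by total divergence t.  No stop
#' codons are ever emitted (the state space is the 61 sense codons).
#'
#' @param nCodons number of codons
#' @param omega nonsynonymous/synonymous rate ratio (> 0)
#' @param kappa transition/transversion ratio (> 0)
#' @param t total divergence between the pair, substitutions per codon (>= 0)
#' @param seed integer seed
#' @param pi stationary codon frequencies (default uniform over the 61
#'   sense codons)
#' @return a \linkS4class{CodonAlignment}
#' @examples
#' pr <- simulateCodonPair(100, omega = 0.3, kappa = 2, t = 0.5, seed = 1)
#' @export
simulateCodonPair <- function(nCodons, omega, kappa, t, seed = 1L, pi = NULL) {
  stopifnot(nCodons >= 1L, omega > 0, kappa > 0, t >= 0)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  set.seed(seed %% 2147483647)
  anc <- sample.int(61L, nCodons, replace = TRUE, prob = pi)
  if (t > 0) {
    eg <- .m0Eigen(pi, kappa, omega)
    P <- .m0Prob(eg, t)
    P <- P / rowSums(P)
    der <- vapply(anc, function(i) sample.int(61L, 1L, prob = P[i, ]), integer(1))
  } else {
    der <- anc
  }
  codonAlignment(paste(.codonData$sense[anc], collapse = ""),
                 paste(.codonData$sense[der], collapse = ""))
}

## ---------------------------------------------------------------------------
## On-disk export
## ---------------------------------------------------------------------------

#' Write a simulated dataset to disk
#'
#' Writes per-species assemblies (FASTA), the truth table (BED, 0-based
#' half-open, name = species:family:status), tRNA genes (GFF3, 1-based),
#' the TE library and host CDS pairs (FASTA), and the species tree
#' (Newick).  Requires the rtracklayer package for BED/GFF3 export.
#'
#' @param dataset result of \code{\link{simulateDataset}}
#' @param outdir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
writeDataset <- function(dataset, outdir) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED/GFF3 export")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in names(dataset$assemblies)) {
    f <- file.path(outdir, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(dataset$assemblies[[sp]], f)
    files <- c(files, f)
  }
  if (length(dataset$truth)) {
    bed <- dataset$truth
    names(bed) <- paste(bed$species, bed$family, bed$status, sep = ":")
    f <- file.path(outdir, "truth.bed")
    rtracklayer::export(bed, f, format = "BED")
    files <- c(files, f)
  }
  if (length(dataset$trna)) {
    gr <- dataset$trna
    gr$type <- "tRNA_gene"
    f <- file.path(outdir, "trna.gff3")
    rtracklayer::export(gr, f, format = "GFF3")
    files <- c(files, f)
  }
  f <- file.path(outdir, "library.fasta")
  Biostrings::writeXStringSet(dataset$library, f)
  files <- c(files, f)
  if (length(dataset$cdsPairs)) {
    seqs <- unlist(lapply(seq_along(dataset$cdsPairs), function(i) {
      p <- dataset$cdsPairs[[i]]
      setNames(c(p@seq1, p@seq2), paste0("pair", i, "_", p@labels))
    }))
    f <- file.path(outdir, "cds_pairs.fasta")
    Biostrings::writeXStringSet(DNAStringSet(seqs), f)
    files <- c(files, f)
  }
  if (!is.null(dataset$speciesTree)) {
    f <- file.path(outdir, "species_tree.nwk")
    ape::write.tree(dataset$speciesTree, f)
    files <- c(files, f)
  }
  invisible(files)
}
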