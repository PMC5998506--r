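## De novo structural detection of full-length LTR elements: direct-repeat
## (LTR pair) discovery via shared k-mer anchoring, ungapped pair
## verification, TSD-guided boundary refinement, plus TSD extraction for
## known intervals and tRNA-proximity analysis.

#' @include AllClasses.R annotate.R
NULL

#' Structural detection parameters
#'
#' @param ltrLenRange min/max LTR length in bp (default 100-1000, covering
#'   the ~293 bp LTRs of yeast Ty4/Tsu4-like families)
#' @param elementLenRange min/max full element length in bp (default
#'   4000-15000, covering ~6 kb elements)
#' @param ltrPairMinIdentity minimum identity between the two LTRs
#' @param tsdLengthBp target site duplication length (default 5)
#' @param tsdMaxMismatch mismatches tolerated in the TSD comparison
#' @param trnaWindowBp tRNA association window (default 1000, i.e. +/-1 kb)
#' @param seedKmerLen anchor k-mer length
#' @param maxKmerOcc k-mers occurring more often than this per chromosome
#'   are skipped as repeats
#' @return named list of validated parameters
#' @export
structuralParams <- function(ltrLenRange = c(100L, 1000L),
                             elementLenRange = c(4000L, 15000L),
                             ltrPairMinIdentity = 0.8,
                             tsdLengthBp = 5L, tsdMaxMismatch = 0L,
                             trnaWindowBp = 1000L, seedKmerLen = 15L,
                             maxKmerOcc = 60L) {
  if (ltrLenRange[1L] > ltrLenRange[2L] ||
      elementLenRange[1L] > elementLenRange[2L])
    stop("min > max in a length range")
  stopifnot(tsdLengthBp >= 0L)
  list(ltrLenRange = as.integer(ltrLenRange),
       elementLenRange = as.integer(elementLenRange),
       ltrPairMinIdentity = ltrPairMinIdentity,
       tsdLengthBp = as.integer(tsdLengthBp),
       tsdMaxMismatch = as.integer(tsdMaxMismatch),
       trnaWindowBp = as.integer(trnaWindowBp),
       seedKmerLen = as.integer(seedKmerLen),
       maxKmerOcc = as.integer(maxKmerOcc))
}

## TSD-guided boundary refinement: look for an exact-length duplication at
## small offsets around the extended boundaries; returns c(start, end, tsd)
## or NULL.
.refineTSD <- function(codes, s, e, tsdLen, maxMM, radius = 6L) {
  if (tsdLen == 0L) return(NULL)
  best <- NULL; bestCost <- Inf
  for (d1 in -radius:radius) {
    ss <- s + d1
    if (ss - tsdLen < 1L) next
    left <- codes[(ss - tsdLen):(ss - 1L)]
    if (anyNA(left)) next
    for (d2 in -radius:radius) {
      ee <- e + d2
      if (ee + tsdLen > length(codes)) next
      right <- codes[(ee + 1L):(ee + tsdLen)]
      if (anyNA(right)) next
      if (sum(left != right) <= maxMM) {
        cost <- abs(d1) + abs(d2)
        if (cost < bestCost) {
          bestCost <- cost
          best <- list(start = ss, end = ee, tsd = .codesToSeq(left))
        }
      }
    }
  }
  best
}

#' De novo detection of full-length LTR element candidates
#'
#' Finds direct-repeat pairs by anchoring shared k-mers at a common
#' separation within the configured element length range, verifies each
#' pair by ungapped extension, and tests the flanks for a target site
#' duplication.  When a TSD is found within a few bp of the extended
#' boundaries, the boundaries snap to it.  Overlapping candidates are
#' resolved to the highest-scoring non-overlapping set.
#'
#' @param assembly \code{DNAStringSet}
#' @param params result of \code{\link{structuralParams}}
#' @return \code{GRanges} of candidates with metadata columns
#'   \code{ltr5Start}, \code{ltr5End}, \code{ltr3Start}, \code{ltr3End},
#'   \code{ltrIdentity} (fraction) and \code{tsd} (NA when absent)
#' @export
detectLTRCandidates <- function(assembly, params = structuralParams()) {
  k <- params$seedKmerLen
  dMin <- params$elementLenRange[1L] - params$ltrLenRange[2L]
  dMax <- params$elementLenRange[2L] - params$ltrLenRange[1L]
  res <- list()
  for (ch in names(assembly)) {
    codes <- .seqToCodes(as.character(assembly[[ch]]))
    h <- .kmerHashes(codes, k)
    o <- order(h, na.last = NA)
    hs <- h[o]
    runStart <- which(c(TRUE, hs[-1L] != hs[-length(hs)]))
    runLen <- diff(c(runStart, length(hs) + 1L))
    p1 <- integer(0); p2 <- integer(0)
    for (r in seq_along(runStart)) {
      m <- runLen[r]
      if (m < 2L || m > params$maxKmerOcc) next
      pos <- sort(o[runStart[r]:(runStart[r] + m - 1L)])
      pr <- outer(pos, pos, function(a, b) b - a)
      ok <- which(pr >= dMin & pr <= dMax, arr.ind = TRUE)
      if (nrow(ok)) {
        p1 <- c(p1, pos[ok[, 1L]])
        p2 <- c(p2, pos[ok[, 2L]])
      }
    }
    if (!length(p1)) next
    sep <- p2 - p1
    o2 <- order(sep, p1)
    p1 <- p1[o2]; p2 <- p2[o2]; sep <- sep[o2]
    newc <- c(TRUE, diff(sep) != 0L | diff(p1) > 100L)
    cid <- cumsum(newc)
    cands <- list()
    for (ii in split(seq_along(p1), cid)) {
      a1 <- min(p1[ii]); a2 <- max(p1[ii]) + k - 1L
      d <- sep[ii][1L]
      ## extend the repeat pair along its diagonal
      b <- .xdropExtend(codes, codes, a1, a2, a1 + d, a2 + d, 20)
      ltrLen <- b[2L] - b[1L] + 1L
      if (ltrLen < params$ltrLenRange[1L] || ltrLen > params$ltrLenRange[2L])
        next
      s <- b[1L]; e <- b[4L]           # element: start of 5' LTR .. end of 3' LTR
      elemLen <- e - s + 1L
      if (elemLen < params$elementLenRange[1L] ||
          elemLen > params$elementLenRange[2L]) next
      ident <- mean(codes[b[1L]:b[2L]] == codes[b[3L]:b[4L]], na.rm = TRUE)
      if (is.na(ident) || ident < params$ltrPairMinIdentity) next
      tsd <- NA_character_
      ref <- .refineTSD(codes, s, e, params$tsdLengthBp, params$tsdMaxMismatch)
      if (!is.null(ref)) {
        shift5 <- ref$start - s
        shift3 <- ref$end - e
        s <- ref$start; e <- ref$end
        b[1L] <- b[1L] + shift5; b[3L] <- b[3L] + shift5
        b[2L] <- b[2L] + shift3; b[4L] <- b[4L] + shift3
        tsd <- ref$tsd
      }
      cands[[length(cands) + 1L]] <- data.frame(
        start = s, end = e, ltr5Start = b[1L], ltr5End = b[2L],
        ltr3Start = b[3L], ltr3End = b[4L], ltrIdentity = ident,
        tsd = tsd, score = ltrLen * ident + 10 * !is.na(tsd))
    }
    if (!length(cands)) next
    df <- do.call(rbind, cands)
    df <- unique(df)
    df <- .selectNonOverlapping(df, df$score)
    res[[length(res) + 1L]] <- cbind(df, chrom = ch)
  }
  if (!length(res)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(ltr5Start = integer(0), ltr5End = integer(0),
                                      ltr3Start = integer(0), ltr3End = integer(0),
                                      ltrIdentity = numeric(0), tsd = character(0))
    return(gr)
  }
  df <- do.call(rbind, res)
  gr <- GRanges(seqnames = df$chrom, ranges = IRanges(df$start, df$end),
                strand = "+", ltr5Start = df$ltr5Start, ltr5End = df$ltr5End,
                ltr3Start = df$ltr3Start, ltr3End = df$ltr3End,
                ltrIdentity = df$ltrIdentity, tsd = df$tsd)
  sort(gr, ignore.strand = TRUE)
}

#' Confirm full-length annotations with structural candidates
#'
#' Returns the full-length annotations that reciprocally overlap a
#' structural LTR candidate by at least \code{minReciprocalOverlap}; the
#' candidate's TSD is copied onto the annotation.  This is the
#' annotation-by-homology x detection-by-structure intersection used to
#' define confirmed full-length elements.
#'
#' @param annotations a \linkS4class{TEAnnotation}
#' @param candidates \code{GRanges} from \code{\link{detectLTRCandidates}}
#' @param minReciprocalOverlap fraction of both intervals that must overlap
#' @return a \linkS4class{TEAnnotation} of confirmed full-length copies
#' @export
intersectCandidates <- function(annotations, candidates,
                                minReciprocalOverlap = 0.5) {
  full <- annotations[annotations$status == "full"]
  if (!length(full) || !length(candidates)) return(full[integer(0)])
  ov <- GenomicRanges::findOverlaps(full, candidates, ignore.strand = TRUE)
  if (!length(ov)) return(full[integer(0)])
  iw <- width(IRanges::pintersect(
    IRanges(start(full)[queryHits(ov)], end(full)[queryHits(ov)]),
    IRanges(start(candidates)[subjectHits(ov)], end(candidates)[subjectHits(ov)])))
  recip <- iw / pmax(width(full)[queryHits(ov)], 1) >= minReciprocalOverlap &
    iw / pmax(width(candidates)[subjectHits(ov)], 1) >= minReciprocalOverlap
  ov <- ov[recip]
  if (!length(ov)) return(full[integer(0)])
  keep <- unique(queryHits(ov))
  out <- full[keep]
  firstCand <- vapply(keep, function(q)
    subjectHits(ov)[which(queryHits(ov) == q)[1L]], integer(1))
  out$tsd <- candidates$tsd[firstCand]
  out
}

#' Target site duplication lookup for a known interval
#'
#' Compares the \code{tsdLengthBp} bases immediately 5' of the interval
#' with those immediately 3' of it; returns the duplication when they match
#' within \code{tsdMaxMismatch} mismatches, else \code{NA}.  Intervals too
#' close to a contig edge return \code{NA} with a warning.
#'
#' @param assembly \code{DNAStringSet}
#' @param interval single-range \code{GRanges} (strand-aware: the reported
#'   TSD reads in element orientation)
#' @param params result of \code{\link{structuralParams}}
#' @return character TSD or \code{NA}
#' @export
findTSD <- function(assembly, interval, params = structuralParams()) {
  stopifnot(length(interval) == 1L)
  tsdLen <- params$tsdLengthBp
  ch <- as.character(GenomicRanges::seqnames(interval))
  seq <- assembly[[ch]]
  s <- start(interval); e <- end(interval)
  if (s - tsdLen < 1L || e + tsdLen > length(seq)) {
    warning("interval at contig edge: no flanking sequence for TSD")
    return(NA_character_)
  }
  left <- as.character(Biostrings::subseq(seq, s - tsdLen, s - 1L))
  right <- as.character(Biostrings::subseq(seq, e + 1L, e + tsdLen))
  mm <- sum(strsplit(left, "")[[1L]] != strsplit(right, "")[[1L]])
  if (mm > params$tsdMaxMismatch) return(NA_character_)
  if (as.character(strand(interval)) == "-") .revcompChar(left) else left
}

#' tRNA proximity of TE annotations
#'
#' Distance from each annotation to the nearest tRNA gene on the same
#' chromosome (edge-to-edge gap; 0 when overlapping or abutting), and
#' whether it falls within the association window (default +/- 1 kb).
#'
#' @param annotations \code{GRanges} or \linkS4class{TEAnnotation}
#' @param trna \code{GRanges} of tRNA genes
#' @param windowBp association window (default from the +/- 1 kb rule)
#' @return data.frame with columns index, chrom, start, end,
#'   nearestTrnaDistance (NA when no tRNA shares the chromosome) and
#'   withinWindow
#' @export
trnaProximity <- function(annotations, trna, windowBp = 1000L) {
  n <- length(annotations)
  dist <- rep(NA_integer_, n)
  if (length(trna)) {
    hit <- GenomicRanges::distanceToNearest(granges(annotations), granges(trna),
                                            ignore.strand = TRUE)
    dist[queryHits(hit)] <- mcols(hit)$distance
  } else {
    warning("empty tRNA set: distances undefined")
  }
  data.frame(index = seq_len(n),
             chrom = as.character(GenomicRanges::seqnames(annotations)),
             start = start(annotations), end = end(annotations),
             nearestTrnaDistance = dist,
             withinWindow = !is.na(dist) & dist <= windowBp)
}
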