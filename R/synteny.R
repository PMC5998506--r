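## Anchor-based whole-genome comparison: unique exact matches (MUM-style),
## co-linear chaining into synteny blocks, translocation-breakpoint
## localization, TE-breakpoint association, and subgenome assignment of
## hybrid scaffolds.

#' @include AllClasses.R
NULL

#' Synteny parameters
#'
#' @param anchorKmerLen anchor seed length (default 21)
#' @param minBlockLenBp minimum synteny block length (default 2000, the
#'   conventional whole-genome-alignment length filter)
#' @param maxAnchorGapBp maximum gap between chained anchors (default 10000)
#' @return named list of validated parameters
#' @export
syntenyParams <- function(anchorKmerLen = 21L, minBlockLenBp = 2000L,
                          maxAnchorGapBp = 10000L) {
  stopifnot(anchorKmerLen > 0L, minBlockLenBp > 0L, maxAnchorGapBp > 0L)
  list(anchorKmerLen = as.integer(anchorKmerLen),
       minBlockLenBp = as.integer(minBlockLenBp),
       maxAnchorGapBp = as.integer(maxAnchorGapBp))
}

## k-mer position table for a DNAStringSet: hash vector per sequence plus a
## combined occurrence count across the whole genome.
.genomeKmers <- function(seqs, k) {
  hashes <- lapply(names(seqs), function(ch)
    .kmerHashes(.seqToCodes(as.character(seqs[[ch]])), k))
  names(hashes) <- names(seqs)
  hashes
}

## Values occurring exactly once over both strands (a match is ambiguous if
## its k-mer occurs anywhere else in the genome, in either orientation).
.uniqueHashes <- function(seqs, k, fwdHashes) {
  rev <- lapply(names(seqs), function(ch)
    .kmerHashes(.seqToCodes(.revcompChar(as.character(seqs[[ch]]))), k))
  all <- c(unlist(fwdHashes, use.names = FALSE), unlist(rev, use.names = FALSE))
  all <- sort(all[!is.na(all)])
  n <- length(all)
  if (!n) return(numeric(0))
  single <- c(all[-1L] != all[-n], TRUE) & c(TRUE, all[-1L] != all[-n])
  all[single]
}

#' Find unique exact anchor matches between two genomes
#'
#' MUM-style anchors: runs of k-mers that occur exactly once in each
#' genome and match between them, merged along diagonals into maximal
#' exact matches, on both strands.  Coordinates are forward (query)
#' coordinates; minus-strand anchors report the target interval of the
#' reverse-complemented match.
#'
#' @param query,target \code{DNAStringSet} genomes (named chromosomes)
#' @param params result of \code{\link{syntenyParams}}
#' @return data.frame with columns qchrom, qstart, qend, tchrom, tstart,
#'   tend, strand, length (1-based inclusive coordinates)
#' @export
findAnchors <- function(query, target, params = syntenyParams()) {
  k <- params$anchorKmerLen
  if (!length(query) || !length(target)) stop("empty genome")
  if (is.null(names(query))) names(query) <- paste0("q", seq_along(query))
  if (is.null(names(target))) names(target) <- paste0("t", seq_along(target))
  qh <- .genomeKmers(query, k)
  th <- .genomeKmers(target, k)
  qUnique <- .uniqueHashes(query, k, qh)
  tUnique <- .uniqueHashes(target, k, th)
  shared <- intersect(qUnique, tUnique)
  ## anchors need a forward-target occurrence (query is scanned in both
  ## orientations, so target-minus matches are covered symmetrically)
  shared <- shared[shared %in% unlist(th, use.names = FALSE)]
  ## target position lookup for shared unique k-mers
  tpos <- list()
  for (ch in names(th)) {
    hit <- which(th[[ch]] %in% shared)
    if (length(hit))
      tpos[[ch]] <- setNames(hit, as.character(th[[ch]][hit]))
  }
  tmap <- unlist(lapply(names(tpos), function(ch)
    setNames(tpos[[ch]], names(tpos[[ch]]))), use.names = TRUE)
  tchromOf <- unlist(lapply(names(tpos), function(ch)
    setNames(rep(ch, length(tpos[[ch]])), names(tpos[[ch]]))))
  out <- list()
  for (qch in names(qh)) {
    hv <- qh[[qch]]
    qlenCh <- length(hv) + k - 1L
    for (strandSym in c("+", "-")) {
      hvs <- if (strandSym == "+") hv else {
        rc <- .kmerHashes(.seqToCodes(.revcompChar(as.character(query[[qch]]))), k)
        rc
      }
      hit <- which(hvs %in% shared)
      if (!length(hit)) next
      key <- as.character(hvs[hit])
      tp <- unname(tmap[key])
      tch <- unname(tchromOf[key])
      ## forward-orient query positions
      qp <- if (strandSym == "+") hit else qlenCh - (hit + k - 1L) + 1L
      ## merge runs: same target chromosome and same diagonal, contiguous
      ## (in scan space the reverse-complemented query aligns forward, so
      ## the diagonal is tp - hit on both strands)
      diagv <- tp - hit
      o <- order(tch, diagv, hit)
      hit <- hit[o]; tp <- tp[o]; tch <- tch[o]; dg <- diagv[o]
      newRun <- c(TRUE, tch[-1L] != tch[-length(tch)] |
                    dg[-1L] != dg[-length(dg)] |
                    diff(hit) != 1L)
      rid <- cumsum(newRun)
      for (ii in split(seq_along(hit), rid)) {
        h1 <- hit[ii[1L]]; h2 <- hit[ii[length(ii)]]
        t1 <- tp[ii[1L]]; t2 <- tp[ii[length(ii)]]
        len <- h2 - h1 + k
        if (strandSym == "+") {
          out[[length(out) + 1L]] <- data.frame(
            qchrom = qch, qstart = h1, qend = h2 + k - 1L,
            tchrom = tch[ii[1L]], tstart = t1, tend = t2 + k - 1L,
            strand = "+", length = len)
        } else {
          ## h indexes the reverse-complemented query
          qs <- qlenCh - (h2 + k - 1L) + 1L
          qe <- qlenCh - h1 + 1L
          out[[length(out) + 1L]] <- data.frame(
            qchrom = qch, qstart = qs, qend = qe,
            tchrom = tch[ii[1L]], tstart = t1, tend = t2 + k - 1L,
            strand = "-", length = len)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(qchrom = character(0), qstart = integer(0),
                      qend = integer(0), tchrom = character(0),
                      tstart = integer(0), tend = integer(0),
                      strand = character(0), length = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$qchrom, df$qstart, df$tchrom, df$tstart), , drop = FALSE]
}

#' Chain anchors into synteny blocks
#'
#' Greedy co-linear chaining per (query chromosome, target chromosome,
#' strand): anchors sorted by query position join a chain while query and
#' target gaps stay within \code{maxAnchorGapBp} and target order is
#' consistent with the strand.  Chains shorter than \code{minBlockLenBp}
#' are dropped; query-overlapping blocks are resolved one-to-one by
#' anchored bases.
#'
#' @param anchors data.frame from \code{\link{findAnchors}}
#' @param params result of \code{\link{syntenyParams}}
#' @return data.frame with columns qchrom, qstart, qend, tchrom, tstart,
#'   tend, strand, nAnchors, anchoredBases
#' @export
chainBlocks <- function(anchors, params = syntenyParams()) {
  if (!nrow(anchors)) {
    return(data.frame(qchrom = character(0), qstart = integer(0),
                      qend = integer(0), tchrom = character(0),
                      tstart = integer(0), tend = integer(0),
                      strand = character(0), nAnchors = integer(0),
                      anchoredBases = integer(0)))
  }
  gmax <- params$maxAnchorGapBp
  blocks <- list()
  for (key in unique(paste(anchors$qchrom, anchors$tchrom, anchors$strand))) {
    a <- anchors[paste(anchors$qchrom, anchors$tchrom, anchors$strand) == key, ,
                 drop = FALSE]
    a <- a[order(a$qstart), , drop = FALSE]
    cid <- integer(nrow(a)); cur <- 1L; cid[1L] <- 1L
    for (i in seq_len(nrow(a))[-1L]) {
      prev <- which(cid == cur)
      prev <- prev[length(prev)]
      qgap <- a$qstart[i] - a$qend[prev]
      tOK <- if (a$strand[i] == "+") {
        a$tstart[i] > a$tstart[prev] &&
          a$tstart[i] - a$tend[prev] <= gmax && a$tstart[i] - a$tend[prev] > -k0(a, prev, i)
      } else {
        a$tend[i] < a$tend[prev] &&
          a$tstart[prev] - a$tend[i] <= gmax && a$tstart[prev] - a$tend[i] > -k0(a, prev, i)
      }
      if (qgap <= gmax && qgap > -(a$qend[prev] - a$qstart[prev]) && tOK) {
        cid[i] <- cur
      } else {
        cur <- cur + 1L; cid[i] <- cur
      }
    }
    for (cc in unique(cid)) {
      m <- which(cid == cc)
      qs <- min(a$qstart[m]); qe <- max(a$qend[m])
      if (qe - qs + 1L < params$minBlockLenBp) next
      blocks[[length(blocks) + 1L]] <- data.frame(
        qchrom = a$qchrom[1L], qstart = qs, qend = qe,
        tchrom = a$tchrom[1L], tstart = min(a$tstart[m]),
        tend = max(a$tend[m]), strand = a$strand[1L],
        nAnchors = length(m),
        anchoredBases = .unionLength(a$qstart[m] - 1L, a$qend[m]))
    }
  }
  if (!length(blocks)) {
    return(chainBlocks(anchors[0, , drop = FALSE], params))
  }
  df <- do.call(rbind, blocks)
  ## one-to-one filtering on the query side: drop lower-scoring overlaps
  df <- df[order(-df$anchoredBases), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) for (j in (i + 1L):nrow(df)) {
      if (!keep[j] || df$qchrom[j] != df$qchrom[i]) next
      ovl <- min(df$qend[i], df$qend[j]) - max(df$qstart[i], df$qstart[j]) + 1L
      if (ovl > 0.5 * (df$qend[j] - df$qstart[j] + 1L)) keep[j] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$qchrom, df$qstart), , drop = FALSE]
}

## helper: tolerated small target-side overlap when chaining (anchor length)
k0 <- function(a, prev, i) {
  max(a$qend[prev] - a$qstart[prev], a$qend[i] - a$qstart[i]) + 1L
}

#' Localize translocation breakpoints between synteny blocks
#'
#' For adjacent blocks on a query chromosome whose target chromosomes
#' differ, reports the interval between them as an approximate breakpoint.
#' Reciprocal partners (a second breakpoint with the two target
#' chromosomes swapped) are cross-referenced.
#'
#' @param blocks data.frame from \code{\link{chainBlocks}}
#' @return data.frame with columns qchrom, intervalStart, intervalEnd,
#'   leftTarget, rightTarget, reciprocalOf (row index or NA)
#' @export
findBreakpoints <- function(blocks) {
  out <- list()
  for (qch in unique(blocks$qchrom)) {
    b <- blocks[blocks$qchrom == qch, , drop = FALSE]
    b <- b[order(b$qstart), , drop = FALSE]
    if (nrow(b) < 2L) next
    for (i in seq_len(nrow(b) - 1L)) {
      if (b$tchrom[i] == b$tchrom[i + 1L]) next
      out[[length(out) + 1L]] <- data.frame(
        qchrom = qch, intervalStart = b$qend[i] + 1L,
        intervalEnd = max(b$qstart[i + 1L] - 1L, b$qend[i] + 1L),
        leftTarget = b$tchrom[i], rightTarget = b$tchrom[i + 1L])
    }
  }
  if (!length(out)) {
    return(data.frame(qchrom = character(0), intervalStart = integer(0),
                      intervalEnd = integer(0), leftTarget = character(0),
                      rightTarget = character(0), reciprocalOf = integer(0)))
  }
  df <- do.call(rbind, out)
  df$reciprocalOf <- NA_integer_
  for (i in seq_len(nrow(df))) {
    j <- which(df$leftTarget == df$rightTarget[i] &
                 df$rightTarget == df$leftTarget[i])
    j <- setdiff(j, i)
    if (length(j)) df$reciprocalOf[i] <- j[1L]
  }
  df
}

#' Associate TE annotations with translocation breakpoints
#'
#' Reports, per breakpoint, the TE copies overlapping the breakpoint
#' interval extended by \code{flankBp}; per reciprocal translocation,
#' whether both breakpoints contain a full-length element and whether the
#' two elements' orientations are compatible with a single ectopic
#' exchange (equal relative orientation across the junction pair).
#'
#' @param breakpoints data.frame from \code{\link{findBreakpoints}}
#' @param annotations a \linkS4class{TEAnnotation} in query coordinates
#' @param flankBp flank added to each breakpoint interval (default 0:
#'   the element must overlap the interval itself)
#' @return list with \code{perBreakpoint} (data.frame: breakpoint index,
#'   TE family/status/strand or NA) and \code{perTranslocation}
#'   (data.frame: the two breakpoint indices, bothBreakpointsFullLength,
#'   orientationConsistent)
#' @export
associateTE <- function(breakpoints, annotations, flankBp = 0L) {
  per <- list()
  teOf <- vector("list", nrow(breakpoints))
  for (i in seq_len(nrow(breakpoints))) {
    win <- GRanges(breakpoints$qchrom[i],
                   IRanges(max(1L, breakpoints$intervalStart[i] - flankBp),
                           breakpoints$intervalEnd[i] + flankBp))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(win, granges(annotations),
                                  ignore.strand = TRUE))
    hits <- subjectHits(ov)
    teOf[[i]] <- hits
    if (length(hits)) {
      per[[length(per) + 1L]] <- data.frame(
        breakpoint = i, family = annotations$family[hits],
        status = annotations$status[hits],
        strand = as.character(strand(annotations))[hits])
    } else {
      per[[length(per) + 1L]] <- data.frame(
        breakpoint = i, family = NA_character_, status = NA_character_,
        strand = NA_character_)
    }
  }
  perBreakpoint <- if (length(per)) do.call(rbind, per) else
    data.frame(breakpoint = integer(0), family = character(0),
               status = character(0), strand = character(0))
  ## reciprocal pairs
  pairs <- list()
  seen <- logical(nrow(breakpoints))
  for (i in seq_len(nrow(breakpoints))) {
    j <- breakpoints$reciprocalOf[i]
    if (is.na(j) || seen[i] || seen[j]) next
    seen[i] <- seen[j] <- TRUE
    fullI <- teOf[[i]][annotations$status[teOf[[i]]] == "full"]
    fullJ <- teOf[[j]][annotations$status[teOf[[j]]] == "full"]
    both <- length(fullI) > 0L && length(fullJ) > 0L
    orient <- if (both) {
      as.character(strand(annotations))[fullI[1L]] ==
        as.character(strand(annotations))[fullJ[1L]]
    } else NA
    pairs[[length(pairs) + 1L]] <- data.frame(
      breakpointA = i, breakpointB = j,
      bothBreakpointsFullLength = both, orientationConsistent = orient)
  }
  perTranslocation <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(breakpointA = integer(0), breakpointB = integer(0),
               bothBreakpointsFullLength = logical(0),
               orientationConsistent = logical(0))
  list(perBreakpoint = perBreakpoint, perTranslocation = perTranslocation)
}

#' Assign hybrid scaffolds to parent subgenomes
#'
#' Anchors each scaffold against a pan-genome whose sequences are labelled
#' by parent species ("parent#chrom") and assigns the scaffold to the
#' parent with the most anchored bases.  Ties are "ambiguous"; scaffolds
#' with no anchors are "unassigned".
#'
#' @param scaffolds \code{DNAStringSet}
#' @param pangenome \code{DNAStringSet} with names \code{parent#chrom}
#' @param params result of \code{\link{syntenyParams}}
#' @return data.frame with columns scaffold, bestParent, margin, and one
#'   anchored-bases column per parent
#' @export
assignSubgenome <- function(scaffolds, pangenome, params = syntenyParams()) {
  parents <- vapply(strsplit(names(pangenome), "#", fixed = TRUE),
                    `[`, "", 1L)
  rows <- list()
  for (si in seq_along(scaffolds)) {
    sc <- scaffolds[si]
    if (is.null(names(sc)) || !nzchar(names(sc))) names(sc) <- paste0("scaffold", si)
    anch <- findAnchors(sc, pangenome, params)
    bases <- vapply(unique(parents), function(p) {
      m <- anch$tchrom %in% names(pangenome)[parents == p]
      if (!any(m)) 0L else .unionLength(anch$qstart[m] - 1L, anch$qend[m])
    }, numeric(1))
    if (all(bases == 0)) {
      best <- "unassigned"; margin <- 0
    } else {
      o <- order(-bases)
      if (length(bases) > 1L && bases[o[1L]] == bases[o[2L]]) {
        best <- "ambiguous"; margin <- 0
      } else {
        best <- names(bases)[o[1L]]
        margin <- bases[o[1L]] - if (length(bases) > 1L) bases[o[2L]] else 0
      }
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(scaffold = names(sc), bestParent = best, margin = margin),
      as.data.frame(as.list(bases)))
  }
  do.call(rbind, rows)
}
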