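## Repeat annotation: a seed-and-extend scanner for TE-homologous intervals,
## a RepeatMasker .out parser, merging/classification of hits into
## full-length / truncated / solo-LTR copies, copy-number tables, and the
## coverage/identity screen for a query element.
##
## Coordinates are 1-based closed intervals inside GRanges (the Bioconductor
## convention); BED export converts to 0-based half-open.

#' @include AllClasses.R
NULL

#' Screen/scan parameters
#'
#' @param minQueryCoverage minimum query coverage for \code{screenAssembly}
#'   to call a pass (default 0.80)
#' @param minIdentity minimum identity fraction (default 0.80)
#' @param seedKmerLen exact seed length for the scanner (default 12)
#' @param xDrop score drop-off terminating ungapped extension (match +1,
#'   mismatch -2; default 20)
#' @param seedGapBp maximum gap between seeds merged into one ungapped hit
#'   (default 150)
#' @param minHitLenBp minimum reported hit length (default 50)
#' @return a named list of validated parameters
#' @export
screenParams <- function(minQueryCoverage = 0.80, minIdentity = 0.80,
                         seedKmerLen = 12L, xDrop = 20, seedGapBp = 150L,
                         minHitLenBp = 50L) {
  stopifnot(minQueryCoverage > 0, minQueryCoverage <= 1,
            minIdentity > 0, minIdentity <= 1, seedKmerLen >= 4L)
  list(minQueryCoverage = minQueryCoverage, minIdentity = minIdentity,
       seedKmerLen = as.integer(seedKmerLen), xDrop = xDrop,
       seedGapBp = as.integer(seedGapBp), minHitLenBp = as.integer(minHitLenBp))
}

#' Classification parameters
#'
#' @param fullCoverageMin internal-region coverage above which a copy with
#'   both LTRs is full-length (default 0.95, i.e. the "> 95\%" rule)
#' @param mergeGapBp maximum gap between co-family hits merged into one copy
#'   (default 500)
#' @param minHitLenBp hits shorter than this are dropped before merging
#' @return a named list of validated parameters
#' @export
classificationParams <- function(fullCoverageMin = 0.95, mergeGapBp = 500L,
                                 minHitLenBp = 50L) {
  stopifnot(fullCoverageMin > 0, fullCoverageMin <= 1, mergeGapBp >= 0)
  list(fullCoverageMin = fullCoverageMin, mergeGapBp = as.integer(mergeGapBp),
       minHitLenBp = as.integer(minHitLenBp))
}

## ungapped x-drop extension of [gs, ge] x [qs, qe] along one diagonal;
## returns updated 1-based inclusive bounds
.xdropExtend <- function(gcodes, qcodes, gs, ge, qs, qe, xDrop) {
  ## rightward
  best <- 0; score <- 0
  gl <- length(gcodes); ql <- length(qcodes)
  i <- ge; j <- qe; bi <- ge; bj <- qe
  while (i < gl && j < ql) {
    i <- i + 1L; j <- j + 1L
    a <- gcodes[i]; b <- qcodes[j]
    score <- score + if (!is.na(a) && !is.na(b) && a == b) 1 else -2
    if (score > best) { best <- score; bi <- i; bj <- j }
    if (best - score >= xDrop) break
  }
  ge <- bi; qe <- bj
  ## leftward
  best <- 0; score <- 0
  i <- gs; j <- qs; bi <- gs; bj <- qs
  while (i > 1L && j > 1L) {
    i <- i - 1L; j <- j - 1L
    a <- gcodes[i]; b <- qcodes[j]
    score <- score + if (!is.na(a) && !is.na(b) && a == b) 1 else -2
    if (score > best) { best <- score; bi <- i; bj <- j }
    if (best - score >= xDrop) break
  }
  c(bi, ge, bj, qe)
}

## Seed-and-extend scan of one coded chromosome against one coded library
## segment (already orientation-adjusted); returns a data frame of hits.
.scanSegment <- function(gcodes, ghash, qcodes, k, xDrop, seedGap, minLen) {
  qhash <- .kmerHashes(qcodes, k)
  if (!length(qhash)) return(NULL)
  uq <- unique(qhash[!is.na(qhash)])
  hitIdx <- which(ghash %in% uq)
  if (!length(hitIdx)) return(NULL)
  ## map genome seed positions to query positions (expand multi-occurrence)
  qpos <- split(seq_along(qhash), qhash)
  gkey <- as.character(ghash[hitIdx])
  reps <- lengths(qpos[gkey])
  g <- rep(hitIdx, reps)
  q <- unlist(qpos[gkey], use.names = FALSE)
  diag <- g - q
  o <- order(diag, g)
  g <- g[o]; q <- q[o]; diag <- diag[o]
  ## cluster seeds on the same diagonal
  newClust <- c(TRUE, diff(diag) != 0L | diff(g) > seedGap)
  cl <- cumsum(newClust)
  idx <- split(seq_along(g), cl)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    b <- .xdropExtend(gcodes, qcodes, min(g[ii]), max(g[ii]) + k - 1L,
                      min(q[ii]), max(q[ii]) + k - 1L, xDrop)
    len <- b[2L] - b[1L] + 1L
    if (len < minLen) next
    ident <- mean(gcodes[b[1L]:b[2L]] == qcodes[b[3L]:b[4L]], na.rm = TRUE)
    ## identity floor: spurious seed clusters in unrelated sequence sit far
    ## below any usable homology
    if (is.na(ident) || ident < 0.6) next
    out[[i]] <- c(b, round(100 * ident, 2), length(ii))
  }
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) return(NULL)
  df <- as.data.frame(out)
  colnames(df) <- c("start", "end", "qstart", "qend", "identity", "nSeeds")
  ## deduplicate identical extensions originating from different clusters
  unique(df)
}

## greedy 1D interval selection: keep highest-scoring, drop overlapping
.selectNonOverlapping <- function(df, scores) {
  keep <- logical(nrow(df))
  taken <- IRanges()
  for (i in order(-scores, df$start)) {
    ir <- IRanges(df$start[i], df$end[i])
    if (!length(taken) || !any(IRanges::overlapsAny(ir, taken))) {
      keep[i] <- TRUE
      taken <- c(taken, ir)
    }
  }
  df[keep, , drop = FALSE]
}

#' Scan an assembly for TE-homologous intervals
#'
#' Seed-and-extend local scanner: exact k-mer seeds are chained per
#' diagonal, extended without gaps under an x-drop rule, and resolved to
#' non-overlapping hits per (family, segment, strand).  Reverse-strand hits
#' are reported in forward assembly coordinates with query coordinates in
#' the segment's forward orientation.
#'
#' @param assembly \code{DNAStringSet} of chromosomes
#' @param library \code{DNAStringSet} whose names follow
#'   \code{"family#segment"} with segment \code{"LTR"} or \code{"internal"}
#'   (as produced by \code{\link{simulateDataset}})
#' @param params result of \code{\link{screenParams}}
#' @return \code{GRanges} of hits with metadata columns \code{family},
#'   \code{segment}, \code{qstart}, \code{qend} (1-based in the library
#'   segment), \code{identity} (percent) and \code{nSeeds}
#' @export
findHits <- function(assembly, library, params = screenParams()) {
  if (length(library) == 0L) stop("empty TE library")
  if (is.null(names(library)) || any(!nzchar(names(library))))
    stop("library sequences must be named family#segment")
  k <- params$seedKmerLen
  res <- list()
  for (ch in names(assembly)) {
    seqChar <- toupper(as.character(assembly[[ch]]))
    if (grepl("[^ACGTN]", seqChar)) {
      warning("non-ACGTN symbols in ", ch, " masked")
      seqChar <- gsub("[^ACGTN]", "N", seqChar)
    }
    gcodes <- .baseCodes(strsplit(seqChar, "", fixed = TRUE)[[1L]])
    ghash <- .kmerHashes(gcodes, k)
    for (li in seq_along(library)) {
      nm <- strsplit(names(library)[li], "#", fixed = TRUE)[[1L]]
      fam <- nm[1L]
      segment <- if (length(nm) > 1L) nm[2L] else "internal"
      qlen <- length(library[[li]])
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") as.character(library[[li]])
                else .revcompChar(as.character(library[[li]]))
        qcodes <- .seqToCodes(qseq)
        df <- .scanSegment(gcodes, ghash, qcodes, k, params$xDrop,
                           params$seedGapBp, params$minHitLenBp)
        if (is.null(df) || !nrow(df)) next
        if (strand == "-") {
          tmp <- df$qstart
          df$qstart <- qlen - df$qend + 1L
          df$qend <- qlen - tmp + 1L
        }
        df <- .selectNonOverlapping(df, df$identity / 100 * (df$end - df$start + 1L))
        res[[length(res) + 1L]] <- cbind(df, chrom = ch, strand = strand,
                                         family = fam, segment = segment)
      }
    }
  }
  if (!length(res)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(family = character(0),
                                      segment = character(0),
                                      qstart = integer(0), qend = integer(0),
                                      identity = numeric(0), nSeeds = integer(0))
    return(gr)
  }
  df <- do.call(rbind, res)
  GRanges(seqnames = df$chrom, ranges = IRanges(df$start, df$end),
          strand = df$strand, family = df$family, segment = df$segment,
          qstart = as.integer(df$qstart), qend = as.integer(df$qend),
          identity = df$identity, nSeeds = as.integer(df$nSeeds))
}

## ---------------------------------------------------------------------------
## RepeatMasker .out interoperability
## ---------------------------------------------------------------------------

.rmSegment <- function(repName) {
  if (grepl("[-_](LTR|ltr)$", repName)) "LTR" else "internal"
}

.rmFamily <- function(repName) {
  sub("[-_](LTR|ltr|I|int|internal)$", "", repName)
}

#' Parse a RepeatMasker .out file
#'
#' Reads the whitespace-separated RepeatMasker .out dialect (3-line
#' header).  The "C" orientation maps to the minus strand; repeat names
#' ending in \code{-LTR}/\code{_LTR} are LTR segments, with suffixes
#' \code{-I}, \code{_I}, \code{-int} (or none) treated as internal.
#' Query coordinates (1-based inclusive in the file) populate the returned
#' \code{GRanges} directly.
#'
#' @param path file path
#' @return \code{GRanges} of hits in the same layout as
#'   \code{\link{findHits}} (without \code{nSeeds})
#' @export
readRepeatMaskerOut <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(family = character(0),
                                      segment = character(0),
                                      qstart = integer(0), qend = integer(0),
                                      identity = numeric(0))
    return(gr)
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 14L)
      stop("malformed RepeatMasker row at line ", i + 3L)
    strand <- if (f[9L] == "C") "-" else "+"
    rb <- suppressWarnings(as.integer(gsub("[()]", "", f[12L])))
    re <- suppressWarnings(as.integer(gsub("[()]", "", f[13L])))
    rb2 <- suppressWarnings(as.integer(gsub("[()]", "", f[14L])))
    qcoords <- if (strand == "+") c(rb, re) else c(rb2, re)
    if (any(is.na(c(qcoords, as.integer(f[6L]), as.integer(f[7L])))))
      stop("malformed RepeatMasker row at line ", i + 3L)
    data.frame(chrom = f[5L], start = as.integer(f[6L]), end = as.integer(f[7L]),
               strand = strand, family = .rmFamily(f[10L]),
               segment = .rmSegment(f[10L]),
               qstart = min(qcoords), qend = max(qcoords),
               identity = 100 - as.numeric(f[2L]))
  })
  df <- do.call(rbind, rows)
  GRanges(seqnames = df$chrom, ranges = IRanges(df$start, df$end),
          strand = df$strand, family = df$family, segment = df$segment,
          qstart = df$qstart, qend = df$qend, identity = df$identity)
}

## Writer for the same dialect (fixtures, round-trip tests).
.writeRepeatMaskerOut <- function(hits, path) {
  hdr <- c("   SW  perc perc perc  query     position in query     matching repeat",
           "score  div. del. ins.  sequence  begin  end   (left)   repeat      class/family begin end (left) ID",
           "")
  rows <- vapply(seq_along(hits), function(i) {
    strand <- as.character(strand(hits))[i]
    repName <- paste0(hits$family[i],
                      if (hits$segment[i] == "LTR") "-LTR" else "-I")
    div <- sprintf("%.1f", 100 - hits$identity[i])
    if (strand == "+") {
      rep3 <- sprintf("%d %d (0)", hits$qstart[i], hits$qend[i])
      ori <- "+"
    } else {
      rep3 <- sprintf("(0) %d %d", hits$qend[i], hits$qstart[i])
      ori <- "C"
    }
    sprintf("%5d %s 0.0 0.0 %s %d %d (0) %s %s Unknown %s %d",
            1000L, div, as.character(GenomicRanges::seqnames(hits))[i],
            start(hits)[i], end(hits)[i], ori, repName, rep3, i)
  }, "")
  writeLines(c(hdr, rows), path)
}

## ---------------------------------------------------------------------------
## Merging and classification
## ---------------------------------------------------------------------------

.canonicalList <- function(canonical) {
  if (is(canonical, "CanonicalElement")) canonical <- list(canonical)
  setNames(canonical, vapply(canonical, teFamily, ""))
}

#' Merge repeat hits into copies and classify them
#'
#' Groups co-family hits into TE copies and assigns each copy a status by
#' the canonical-coverage rules: full-length copies have both LTRs and
#' internal-region coverage above \code{fullCoverageMin} (the "> 95\%"
#' rule), truncated copies have internal sequence below that coverage, and
#' solo LTRs have no internal match.  Internal-segment hits are clustered
#' first (gap at most \code{mergeGapBp}); LTR hits attach to the nearest
#' internal cluster within the gap (ties go upstream), and unattached LTR
#' hits form solo-LTR copies.  Internal coverage is the union of
#' internal-segment query intervals divided by the canonical internal
#' length (overlapping fragments are not double-counted).
#'
#' @param hits \code{GRanges} from \code{\link{findHits}} or
#'   \code{\link{readRepeatMaskerOut}}
#' @param canonical a \linkS4class{CanonicalElement} or list thereof
#'   covering every family present in \code{hits}
#' @param params result of \code{\link{classificationParams}}
#' @return a \linkS4class{TEAnnotation}; each input hit is assigned to
#'   exactly one annotation (member indices in \code{memberHits})
#' @export
mergeAndClassify <- function(hits, canonical, params = classificationParams()) {
  canon <- .canonicalList(canonical)
  missing <- setdiff(unique(hits$family), names(canon))
  if (length(missing))
    stop("hits from families absent in canonical set: ",
         paste(missing, collapse = ", "))
  origIdx <- which(width(hits) >= params$minHitLenBp)
  hits <- hits[origIdx]
  rows <- list()
  for (ch in unique(as.character(GenomicRanges::seqnames(hits)))) {
    for (fam in unique(hits$family)) {
      sel <- which(as.character(GenomicRanges::seqnames(hits)) == ch &
                     hits$family == fam)
      if (!length(sel)) next
      h <- hits[sel]
      o <- order(start(h))
      h <- h[o]; sel <- sel[o]
      internalLen <- {
        ir <- internalRegion(canon[[fam]])
        ir[["end"]] - ir[["start"]] + 1L
      }
      isInt <- h$segment == "internal"
      ## cluster internal hits by gap
      intIdx <- which(isInt)
      clustOf <- integer(length(h))
      nClust <- 0L
      if (length(intIdx)) {
        gaps <- c(Inf, start(h)[intIdx][-1L] - cummax(end(h)[intIdx][-length(intIdx)]))
        newc <- gaps > params$mergeGapBp
        cid <- cumsum(newc)
        clustOf[intIdx] <- cid
        nClust <- max(cid)
      }
      ## cluster spans
      spans <- if (nClust) {
        t(vapply(seq_len(nClust), function(cc) {
          m <- intIdx[clustOf[intIdx] == cc]
          c(min(start(h)[m]), max(end(h)[m]))
        }, numeric(2)))
      } else NULL
      ## attach LTR hits to nearest internal cluster within mergeGap
      ltrIdx <- which(!isInt)
      soloSeed <- integer(0)
      for (li in ltrIdx) {
        if (nClust) {
          gap <- pmax(spans[, 1L] - end(h)[li] - 1L,
                      start(h)[li] - spans[, 2L] - 1L, 0L)
          best <- which(gap == min(gap))
          if (min(gap) <= params$mergeGapBp) {
            clustOf[li] <- best[1L]      # ties: lowest-coordinate (upstream)
            next
          }
        }
        soloSeed <- c(soloSeed, li)
      }
      ## unattached LTR hits: cluster among themselves (fragmented solos)
      if (length(soloSeed)) {
        ss <- soloSeed[order(start(h)[soloSeed])]
        gaps <- c(Inf, start(h)[ss][-1L] - cummax(end(h)[ss][-length(ss)]))
        cid <- cumsum(gaps > params$mergeGapBp) + nClust
        clustOf[ss] <- cid
        nClust <- max(cid)
      }
      for (cc in seq_len(nClust)) {
        m <- which(clustOf == cc)
        if (!length(m)) next
        aStart <- min(start(h)[m]); aEnd <- max(end(h)[m])
        str <- names(which.max(table(as.character(strand(h))[m])))
        mInt <- m[h$segment[m] == "internal"]
        cov <- if (length(mInt))
          .unionLength(h$qstart[mInt] - 1L, h$qend[mInt]) / internalLen else 0
        cov <- min(cov, 1)
        mLtr <- m[h$segment[m] == "LTR"]
        intSpan <- if (length(mInt)) c(min(start(h)[mInt]), max(end(h)[mInt]))
                   else c(aStart, aEnd)
        hasLeft <- any(end(h)[mLtr] <= intSpan[1L])
        hasRight <- any(start(h)[mLtr] >= intSpan[2L])
        has5p <- if (str == "-") hasRight else hasLeft
        has3p <- if (str == "-") hasLeft else hasRight
        status <- if (!length(mInt)) "solo"
          else if (has5p && has3p && cov > params$fullCoverageMin) "full"
          else "truncated"
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = aStart, end = aEnd, strand = str, family = fam,
          status = status, internalCoverage = cov,
          has5pLTR = has5p, has3pLTR = has3p,
          memberHits = I(list(origIdx[sel[m]])))
      }
    }
  }
  if (!length(rows)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(family = character(0), status = character(0),
                                      internalCoverage = numeric(0),
                                      has5pLTR = logical(0), has3pLTR = logical(0),
                                      tsd = character(0))
    return(TEAnnotation(gr))
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(seqnames = df$chrom, ranges = IRanges(df$start, df$end),
                strand = df$strand, family = df$family, status = df$status,
                internalCoverage = df$internalCoverage, has5pLTR = df$has5pLTR,
                has3pLTR = df$has3pLTR, tsd = NA_character_,
                memberHits = df$memberHits)
  gr <- sort(gr, ignore.strand = TRUE)
  TEAnnotation(gr)
}

#' Copy-number table per strain and family
#'
#' Counts full-length, truncated and solo-LTR copies per (strain, family),
#' the per-assembly summary layout used for Ty-element content tables.
#'
#' @param annotationsByStrain named list of \linkS4class{TEAnnotation}
#' @param families optional family universe; strains report zero rows for
#'   families without copies
#' @return data.frame with columns strain, family, nFull, nTruncated,
#'   nSolo
#' @export
copyNumberTable <- function(annotationsByStrain, families = NULL) {
  if (is.null(families))
    families <- sort(unique(unlist(lapply(annotationsByStrain,
                                          function(a) unique(a$family)))))
  if (!length(families)) families <- character(0)
  rows <- list()
  for (strain in names(annotationsByStrain)) {
    a <- annotationsByStrain[[strain]]
    for (fam in families) {
      sel <- a$family == fam
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, family = fam,
        nFull = sum(sel & a$status == "full"),
        nTruncated = sum(sel & a$status == "truncated"),
        nSolo = sum(sel & a$status == "solo"))
    }
    if (!length(families))
      rows[[length(rows) + 1L]] <- data.frame(strain = strain, family = NA,
                                              nFull = 0L, nTruncated = 0L,
                                              nSolo = 0L)
  }
  do.call(rbind, rows)
}

#' Coverage/identity screen of an assembly for a query element
#'
#' Scans the assembly for the query, chains hits into loci, and reports
#' per-locus query coverage (union of query intervals over the query
#' length) and weighted mean identity.  A locus passes when coverage and
#' identity both meet their thresholds, the "80/80"-style screen used to
#' find complete or nearly-complete elements.
#'
#' @param assembly \code{DNAStringSet}
#' @param query single-sequence \code{DNAStringSet} (or DNAString)
#' @param params result of \code{\link{screenParams}}
#' @param locusGapBp maximum gap between hits chained into one locus
#' @return data.frame with columns chrom, start, end, strand,
#'   queryCoverage, identity, passes
#' @export
screenAssembly <- function(assembly, query, params = screenParams(),
                           locusGapBp = 1000L) {
  if (is(query, "DNAString")) query <- DNAStringSet(query)
  if (length(query) != 1L) stop("query must contain exactly one sequence")
  qlen <- width(query)[1L]
  names(query) <- "query#internal"
  hits <- findHits(assembly, query, params)
  if (!length(hits)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      queryCoverage = numeric(0), identity = numeric(0),
                      passes = logical(0)))
  }
  rows <- list()
  for (ch in unique(as.character(GenomicRanges::seqnames(hits)))) {
    for (str in c("+", "-")) {
      h <- hits[as.character(GenomicRanges::seqnames(hits)) == ch &
                  as.character(strand(hits)) == str]
      if (!length(h)) next
      h <- h[order(start(h))]
      gaps <- c(Inf, start(h)[-1L] - cummax(end(h)[-length(h)]))
      cid <- cumsum(gaps > locusGapBp)
      for (cc in unique(cid)) {
        m <- which(cid == cc)
        covg <- .unionLength(h$qstart[m] - 1L, h$qend[m]) / qlen
        w <- width(h)[m]
        ident <- sum(h$identity[m] * w) / sum(w) / 100
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = min(start(h)[m]), end = max(end(h)[m]),
          strand = str, queryCoverage = covg, identity = ident,
          passes = covg >= params$minQueryCoverage &
            ident >= params$minIdentity)
      }
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Export annotations as BED
#'
#' One record per copy, name \code{family:status-initial} (f/t/s), the
#' compact convention for per-assembly Ty annotation tracks.  Requires
#' rtracklayer.
#'
#' @param annotations a \linkS4class{TEAnnotation}
#' @param path output BED path
#' @return invisibly, \code{path}
#' @export
writeAnnotationBED <- function(annotations, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED export")
  gr <- GRanges(seqnames = GenomicRanges::seqnames(annotations),
                ranges = IRanges(start(annotations), end(annotations)),
                strand = strand(annotations))
  names(gr) <- paste0(annotations$family, ":",
                      substr(annotations$status, 1L, 1L))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
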