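## Canonical element derivation: center-star multiple alignment of
## full-length copies, majority consensus, canonical-copy selection via a
## neighbor-joining tree, and solo-LTR divergence dating.

#' @include AllClasses.R phylo.R
NULL

.pwGlobal <- function(a, b) {
  Biostrings::pairwiseAlignment(DNAString(a), DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 1)
}

#' Center-star multiple alignment
#'
#' Progressive multiple alignment for low-divergence copies: the medoid
#' sequence (smallest total k-mer distance to the rest) is the center; all
#' other sequences are globally aligned to it and merged under the
#' "once a gap, always a gap" rule.  Adequate for sets of recently diverged
#' element copies; not a general-purpose aligner.
#'
#' @param sequences \code{DNAStringSet} (at least 2; a single sequence is
#'   returned unchanged with a warning)
#' @return named character vector of equal-length aligned rows; removing
#'   gaps restores the inputs exactly
#' @export
alignCopies <- function(sequences) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  n <- length(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0("seq", seq_len(n))
  if (n == 1L) {
    warning("single sequence: returned unchanged")
    return(setNames(as.character(sequences), names(sequences)))
  }
  ## medoid by 4-mer frequency distance
  center <- if (n == 2L) 1L else {
    kf <- Biostrings::oligonucleotideFrequency(sequences, width = 4)
    kf <- kf / pmax(rowSums(kf), 1)
    dd <- as.matrix(stats::dist(kf))
    which.min(rowSums(dd))
  }
  cseq <- as.character(sequences[[center]])
  cLen <- nchar(cseq)
  others <- setdiff(seq_len(n), center)
  alns <- lapply(others, function(i) {
    pa <- .pwGlobal(as.character(sequences[[i]]), cseq)
    list(row = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]],
         ctr = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]])
  })
  ## per-alignment insertion counts before each center position (1..cLen+1)
  insCounts <- matrix(0L, nrow = length(others), ncol = cLen + 1L)
  for (ai in seq_along(alns)) {
    ctr <- alns[[ai]]$ctr
    pos <- 1L; run <- 0L
    for (x in ctr) {
      if (x == "-") run <- run + 1L
      else { insCounts[ai, pos] <- run; run <- 0L; pos <- pos + 1L }
    }
    insCounts[ai, cLen + 1L] <- run
  }
  maxIns <- apply(insCounts, 2L, max)
  if (length(others) == 0L) maxIns <- rep(0L, cLen + 1L)
  width <- cLen + sum(maxIns)
  ## project center row
  centerRow <- character(0)
  cchars <- strsplit(cseq, "")[[1L]]
  for (p in seq_len(cLen))
    centerRow <- c(centerRow, rep("-", maxIns[p]), cchars[p])
  centerRow <- c(centerRow, rep("-", maxIns[cLen + 1L]))
  ## project each other row
  outRows <- matrix("-", nrow = n, ncol = width)
  outRows[center, ] <- centerRow
  for (ai in seq_along(alns)) {
    row <- alns[[ai]]$row; ctr <- alns[[ai]]$ctr
    res <- character(width)
    res[] <- "-"
    col <- 1L; pos <- 1L; pend <- character(0)
    k <- 1L
    for (x in seq_along(ctr)) {
      if (ctr[x] == "-") {
        pend <- c(pend, row[x])
      } else {
        ## flush insertions right-aligned before this center position
        nIns <- maxIns[pos]
        slot <- col + nIns - length(pend)
        if (length(pend)) res[slot:(col + nIns - 1L)] <- pend
        res[col + nIns] <- row[x]
        col <- col + nIns + 1L
        pos <- pos + 1L
        pend <- character(0)
      }
    }
    nIns <- maxIns[cLen + 1L]
    if (length(pend)) res[(col + nIns - length(pend)):(col + nIns - 1L)] <- pend
    outRows[others[ai], ] <- res
  }
  out <- apply(outRows, 1L, paste, collapse = "")
  names(out) <- names(sequences)
  out
}

#' Majority consensus of a multiple alignment
#'
#' Per column, the most frequent non-gap symbol (ties broken by the
#' lexicographically smallest base); columns with gap fraction >= 0.5 are
#' dropped.
#'
#' @param alignment aligned rows (named character vector, matrix, or
#'   \code{DNAStringSet})
#' @return consensus sequence (character)
#' @export
consensusSequence <- function(alignment) {
  m <- .alnMatrix(alignment)
  if (!nrow(m)) stop("empty alignment")
  cons <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gapFrac <- mean(col == "-")
    if (gapFrac >= 0.5) next
    tab <- table(col[col != "-"])
    cons <- c(cons, sort(names(tab)[tab == max(tab)])[1L])
  }
  paste(cons, collapse = "")
}

#' Select the canonical genomic copy
#'
#' Aligns the copies together with the consensus, builds a p-distance
#' neighbor-joining tree, and returns the copy with the smallest patristic
#' (tree-path) distance to the consensus leaf - the copy that "clusters
#' most closely" with the consensus.  Ties are broken by input (genomic
#' coordinate) order.
#'
#' @param copies named \code{DNAStringSet} of full-length copies (>= 2);
#'   names are treated as genomic coordinate labels for tie-breaking
#' @param consensus consensus sequence (character; default: computed from
#'   the copies)
#' @param family family name for the returned element
#' @param ltrLengthBp LTR length recorded on the element
#' @return a \linkS4class{CanonicalElement} whose \code{sourceLocus} is the
#'   selected copy's name
#' @export
selectCanonical <- function(copies, consensus = NULL, family = "family",
                            ltrLengthBp = NA_integer_) {
  stopifnot(length(copies) >= 2L)
  if (is.null(names(copies)) || any(!nzchar(names(copies))))
    names(copies) <- paste0("copy", seq_along(copies))
  w <- width(copies)
  if ((max(w) - min(w)) / max(w) > 0.2)
    warning("copies differ in length by more than 20%")
  if (is.null(consensus)) consensus <- consensusSequence(alignCopies(copies))
  all <- c(copies, DNAStringSet(setNames(consensus, ".consensus")))
  aln <- alignCopies(all)
  d <- pdistanceMatrix(aln)
  tr <- neighborJoining(d)
  pat <- cophenetic(tr)
  dCons <- pat[".consensus", names(copies)]
  best <- which(dCons <= min(dCons) + 1e-12)[1L]   # ties: first by input order
  ltr <- if (is.na(ltrLengthBp)) {
    as.integer(round(width(copies)[best] * 0.05))
  } else as.integer(ltrLengthBp)
  canonicalElement(family, as.character(copies[[best]]), ltr,
                   sourceLocus = names(copies)[best])
}

#' Solo-LTR divergence to the canonical LTR
#'
#' Globally aligns each solo-LTR copy to the canonical LTR and reports the
#' p-distance over aligned non-gap columns.  Copies whose alignment covers
#' less than half of the canonical LTR are excluded and counted.  Because a
#' solo LTR is left behind when a full-length copy recombines away, low
#' solo-LTR divergence marks recent family activity; the summary mean is
#' the per-genome activity clock (reported to 2 decimals in text reports).
#'
#' @param soloSeqs \code{DNAStringSet} of solo-LTR sequences
#' @param canonical a \linkS4class{CanonicalElement}
#' @return list with \code{summary} (data.frame: family, class, n,
#'   meanDivergence, nExcluded) and \code{perCopy} (numeric divergences)
#' @export
soloLtrDivergence <- function(soloSeqs, canonical) {
  ltrSeq <- as.character(Biostrings::subseq(canonicalSequence(canonical), 1L,
                                            ltrLength(canonical)))
  ltrLen <- nchar(ltrSeq)
  div <- numeric(0); excluded <- 0L
  for (i in seq_along(soloSeqs)) {
    pa <- .pwGlobal(as.character(soloSeqs[[i]]), ltrSeq)
    a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    comp <- a != "-" & b != "-"
    if (sum(comp) < 0.5 * ltrLen) { excluded <- excluded + 1L; next }
    div <- c(div, mean(a[comp] != b[comp]))
  }
  nm <- if (!is.null(names(soloSeqs))) names(soloSeqs)[seq_along(div)] else NULL
  list(summary = data.frame(family = teFamily(canonical), class = "solo",
                            n = length(div),
                            meanDivergence = if (length(div)) mean(div) else NA_real_,
                            nExcluded = excluded),
       perCopy = div)
}
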