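## Low-level sequence utilities shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importFrom methods is new validObject setValidity show
#' @importFrom stats runif rbinom rpois setNames median optim cophenetic
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges seqnames
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom BiocGenerics start end width strand sort
NULL

## Convert a character vector of single bases to integer codes A=0,C=1,G=2,T=3
## (NA for anything else).
.baseCodes <- function(x) {
  match(x, DNA_BASES) - 1L
}

.seqToCodes <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  .baseCodes(strsplit(seq, "", fixed = TRUE)[[1L]])
}

.codesToSeq <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

## Rolling k-mer hash over a coded sequence.  Hashes are exact doubles for
## k <= 26 (4^26 < 2^53).  Positions with any non-ACGT base hash to NA.
.kmerHashes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  h <- numeric(m)
  pow <- 1
  for (j in seq_len(k)) {
    h <- h + codes[j:(m + j - 1L)] * pow
    pow <- pow * 4
  }
  h
}

.revcompChar <- function(seq) {
  as.character(reverseComplement(DNAString(seq)))
}

## Jukes-Cantor evolution of a coded sequence by `d` substitutions/site.
## Substitutions are drawn per site with the JC probability of observing a
## difference after distance d; substituted sites get a uniform different base.
.evolveCodes <- function(codes, d, rng = NULL) {
  if (d <= 0) return(codes)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(codes)) < p)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- (codes[hit] + shift) %% 4L
  }
  codes
}

## Random sequence of length n with given ACGT frequencies, as codes.
.randomCodes <- function(n, baseComposition = rep(0.25, 4)) {
  sample.int(4L, n, replace = TRUE, prob = baseComposition) - 1L
}

## p-distance between two equal-length character vectors of bases, ignoring
## positions where either is a gap.
.pDistChars <- function(a, b, gap = "-") {
  keep <- a != gap & b != gap
  if (!any(keep)) return(NA_real_)
  mean(a[keep] != b[keep])
}

## Derive a stream of sub-seeds from one master seed, staying below 2^31.
.deriveSeeds <- function(seed, n) {
  (as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483629
}

## Interval union length of an IRanges-like start/end (0-based half-open)
## given as a two-column matrix.
.unionLength <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; curS <- starts[1L]; curE <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= curE) {
      curE <- max(curE, ends[i])
    } else {
      tot <- tot + (curE - curS)
      curS <- starts[i]; curE <- ends[i]
    }
  }
  tot + (curE - curS)
}
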