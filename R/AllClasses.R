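#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Transposable element family specification
#'
#' Describes one LTR-retrotransposon family for the genome simulator: the
#' structural layout (LTR and internal lengths, TSD length) and the
#' per-lineage dynamics (insertion rate, probabilities that a copy is
#' reduced to a solo LTR or truncated, and the post-insertion divergence
#' scale).
#'
#' @slot name family identifier
#' @slot ltrLengthBp LTR length in bp (yeast Ty4/Tsu4-like default 293)
#' @slot internalLengthBp internal (coding) region length in bp; kept a
#'   multiple of 3 so internal regions can be analysed as codons
#' @slot tsdLengthBp target site duplication length (default 5)
#' @slot insertionRate expected insertions per unit branch length on each
#'   root-to-tip path of the species tree
#' @slot soloFormationProb probability a copy is reduced to a solo LTR by
#'   intra-element LTR-LTR recombination
#' @slot truncationProb probability a copy is 5'-truncated
#' @slot divergenceScale mean post-insertion divergence (substitutions/site)
#'   applied to each copy; per-copy values are drawn uniformly from
#'   \code{[0, 2 * divergenceScale]}
#' @slot presentIn species names in which the family is active, or "all"
#' @export
setClass("FamilySpec",
  representation(
    name = "character",
    ltrLengthBp = "integer",
    internalLengthBp = "integer",
    tsdLengthBp = "integer",
    insertionRate = "numeric",
    soloFormationProb = "numeric",
    truncationProb = "numeric",
    divergenceScale = "numeric",
    presentIn = "character"
  )
)

setValidity("FamilySpec", function(object) {
  msg <- character(0)
  if (object@ltrLengthBp < 1L) msg <- c(msg, "ltrLengthBp must be >= 1")
  if (object@internalLengthBp < 3L) msg <- c(msg, "internalLengthBp must be >= 3")
  if (object@tsdLengthBp < 0L) msg <- c(msg, "tsdLengthBp must be >= 0")
  if (object@insertionRate < 0) msg <- c(msg, "insertionRate must be >= 0")
  p <- c(object@soloFormationProb, object@truncationProb)
  if (any(p < 0) || any(p > 1) || sum(p) > 1)
    msg <- c(msg, "soloFormationProb + truncationProb must lie in [0, 1]")
  if (object@divergenceScale < 0) msg <- c(msg, "divergenceScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param name,ltrLengthBp,internalLengthBp,tsdLengthBp,insertionRate
#'   see slot documentation
#' @param soloFormationProb,truncationProb,divergenceScale,presentIn
#'   see slot documentation
#' @rdname FamilySpec-class
#' @return a validated \code{FamilySpec}
#' @examples
#' familySpec("Tsu4", insertionRate = 10)
#' @export
familySpec <- function(name, ltrLengthBp = 293L, internalLengthBp = 5409L,
                       tsdLengthBp = 5L, insertionRate = 5,
                       soloFormationProb = 0.3, truncationProb = 0.1,
                       divergenceScale = 0.02, presentIn = "all") {
  internalLengthBp <- as.integer(internalLengthBp)
  if (internalLengthBp %% 3L != 0L)
    internalLengthBp <- internalLengthBp + (3L - internalLengthBp %% 3L)
  new("FamilySpec", name = name, ltrLengthBp = as.integer(ltrLengthBp),
      internalLengthBp = internalLengthBp, tsdLengthBp = as.integer(tsdLengthBp),
      insertionRate = insertionRate, soloFormationProb = soloFormationProb,
      truncationProb = truncationProb, divergenceScale = divergenceScale,
      presentIn = presentIn)
}

#' Simulation configuration
#'
#' Full description of one simulated dataset: a species history, per-species
#' genome assemblies with planted TE copies in three states (full-length,
#' truncated, solo LTR), tRNA genes with configurable insertion targeting,
#' an optional horizontal transfer event, host CDS pairs for the synonymous
#' divergence baseline, and optional reciprocal translocations.
#'
#' @slot seed master seed; fully determines all outputs
#' @slot nSpecies number of species (used when \code{speciesTree == "random"})
#' @slot speciesTree Newick string, or "random"
#' @slot speciesDivergence total root-to-tip height (substitutions/site) the
#'   species tree is scaled to
#' @slot genomeLengthBp length of each chromosome in bp
#' @slot nChromosomes chromosomes per assembly
#' @slot baseComposition ACGT frequencies, summing to 1
#' @slot teFamilies list of \linkS4class{FamilySpec}
#' @slot nTrnaGenes tRNA genes per chromosome
#' @slot trnaTargetingProb probability an insertion is placed within the
#'   targeting window (+/- 1 kb) of a tRNA gene
#' @slot httEvent \code{NULL}, or a list with elements \code{donor},
#'   \code{recipient} (species names), \code{family}, \code{time}
#'   (divergence, substitutions/site, since transfer) and \code{burstSize}
#'   (number of post-transfer copies in the recipient)
#' @slot translocations data frame with columns \code{chrA}, \code{posA},
#'   \code{chrB}, \code{posB}, \code{teAtBreakpoints}; applied to the first
#'   species' assembly after TE insertion
#' @slot nCdsPairs number of host CDS pairs emitted (donor vs recipient
#'   lineages, or the two most distant species when no HTT event is set)
#' @slot cdsLengthCodons length of each host CDS in codons
#' @slot minInsertionSpacingBp minimum distance between insertion sites
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nSpecies = "integer",
    speciesTree = "character",
    speciesDivergence = "numeric",
    genomeLengthBp = "integer",
    nChromosomes = "integer",
    baseComposition = "numeric",
    teFamilies = "list",
    nTrnaGenes = "integer",
    trnaTargetingProb = "numeric",
    httEvent = "ANY",
    translocations = "data.frame",
    nCdsPairs = "integer",
    cdsLengthCodons = "integer",
    minInsertionSpacingBp = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (abs(sum(object@baseComposition) - 1) > 1e-9)
    msg <- c(msg, "baseComposition must sum to 1")
  if (any(object@baseComposition < 0))
    msg <- c(msg, "baseComposition must be nonnegative")
  if (object@trnaTargetingProb < 0 || object@trnaTargetingProb > 1)
    msg <- c(msg, "trnaTargetingProb must lie in [0, 1]")
  if (object@nSpecies < 1L) msg <- c(msg, "nSpecies must be >= 1")
  if (!all(vapply(object@teFamilies, is, logical(1), class2 = "FamilySpec")))
    msg <- c(msg, "teFamilies must be a list of FamilySpec objects")
  if (!is.null(object@httEvent)) {
    need <- c("donor", "recipient", "family", "time", "burstSize")
    if (!all(need %in% names(object@httEvent)))
      msg <- c(msg, paste("httEvent must have elements:",
                          paste(need, collapse = ", ")))
  }
  if (nrow(object@translocations) &&
      !all(c("chrA", "posA", "chrB", "posB", "teAtBreakpoints") %in%
           colnames(object@translocations)))
    msg <- c(msg, "translocations needs columns chrA, posA, chrB, posB, teAtBreakpoints")
  if (length(msg)) msg else TRUE
})

#' @param seed,nSpecies,speciesTree,speciesDivergence see slot documentation
#' @param genomeLengthBp,nChromosomes,baseComposition,teFamilies see slots
#' @param nTrnaGenes,trnaTargetingProb,httEvent,translocations see slots
#' @param nCdsPairs,cdsLengthCodons,minInsertionSpacingBp see slots
#' @rdname SimulationConfig-class
#' @return a validated \code{SimulationConfig}
#' @export
simulationConfig <- function(seed = 1L, nSpecies = 4L, speciesTree = "random",
                             speciesDivergence = 0.3,
                             genomeLengthBp = 200000L, nChromosomes = 2L,
                             baseComposition = rep(0.25, 4),
                             teFamilies = list(familySpec("famA")),
                             nTrnaGenes = 4L, trnaTargetingProb = 0.75,
                             httEvent = NULL,
                             translocations = data.frame(),
                             nCdsPairs = 10L, cdsLengthCodons = 200L,
                             minInsertionSpacingBp = 20000L) {
  new("SimulationConfig", seed = as.integer(seed), nSpecies = as.integer(nSpecies),
      speciesTree = speciesTree, speciesDivergence = speciesDivergence,
      genomeLengthBp = as.integer(genomeLengthBp),
      nChromosomes = as.integer(nChromosomes),
      baseComposition = baseComposition, teFamilies = teFamilies,
      nTrnaGenes = as.integer(nTrnaGenes), trnaTargetingProb = trnaTargetingProb,
      httEvent = httEvent, translocations = translocations,
      nCdsPairs = as.integer(nCdsPairs),
      cdsLengthCodons = as.integer(cdsLengthCodons),
      minInsertionSpacingBp = as.integer(minInsertionSpacingBp))
}

## ---------------------------------------------------------------------------
## TEAnnotation: classified TE copies as a GRanges subclass
## ---------------------------------------------------------------------------

#' Classified transposable element annotations
#'
#' A \link[GenomicRanges]{GRanges} subclass holding one classified TE copy
#' per range.  Required metadata columns: \code{family}, \code{status}
#' (\code{"full"}, \code{"truncated"} or \code{"solo"}),
#' \code{internalCoverage} (fraction of the canonical internal region
#' covered), \code{has5pLTR}, \code{has3pLTR} and \code{tsd} (recovered
#' target site duplication, \code{NA} when absent).  Full-length copies have
#' both LTRs; solo LTRs have zero internal coverage.
#'
#' @export
#' @importClassesFrom GenomicRanges GRanges
setClass("TEAnnotation", contains = "GRanges")

setValidity("TEAnnotation", function(object) {
  msg <- character(0)
  need <- c("family", "status", "internalCoverage", "has5pLTR", "has3pLTR", "tsd")
  mc <- S4Vectors::mcols(object)
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (!all(mc$status %in% c("full", "truncated", "solo")))
      msg <- c(msg, "status must be full, truncated or solo")
    bad <- mc$status == "full" & !(mc$has5pLTR & mc$has3pLTR)
    if (any(bad)) msg <- c(msg, "full-length copies must have both LTRs")
    bad <- mc$status == "solo" & mc$internalCoverage != 0
    if (any(bad)) msg <- c(msg, "solo LTRs must have zero internal coverage")
  }
  if (length(msg)) msg else TRUE
})

#' @param gr a \code{GRanges} with the required metadata columns
#' @rdname TEAnnotation-class
#' @return a validated \code{TEAnnotation}
#' @export
TEAnnotation <- function(gr) {
  new("TEAnnotation", gr)
}

## ---------------------------------------------------------------------------
## CanonicalElement
## ---------------------------------------------------------------------------

#' Canonical family element
#'
#' The representative genomic copy of a TE family: its sequence starts and
#' ends with the LTR, with the internal region in between.  Used as the
#' reference for internal-region coverage in classification and for
#' solo-LTR divergence dating.
#'
#' @slot family family name
#' @slot sequence element sequence (\link[Biostrings]{DNAString})
#' @slot ltrLengthBp LTR length in bp
#' @slot internalStart,internalEnd 1-based inclusive bounds of the internal
#'   region within \code{sequence}
#' @slot sourceLocus genomic origin, "chrom:start-end" (1-based), or ""
#' @export
setClass("CanonicalElement",
  representation(
    family = "character",
    sequence = "DNAString",
    ltrLengthBp = "integer",
    internalStart = "integer",
    internalEnd = "integer",
    sourceLocus = "character"
  )
)

setValidity("CanonicalElement", function(object) {
  msg <- character(0)
  L <- length(object@sequence)
  if (object@internalStart < 1L || object@internalEnd > L ||
      object@internalStart > object@internalEnd)
    msg <- c(msg, "internal region must lie inside the sequence")
  if (2L * object@ltrLengthBp > L)
    msg <- c(msg, "two LTRs cannot exceed the element length")
  if (length(msg)) msg else TRUE
})

#' @param family,sequence,ltrLengthBp,sourceLocus see slot documentation
#' @param internalStart,internalEnd internal region bounds; default: everything
#'   between the two LTRs
#' @rdname CanonicalElement-class
#' @return a validated \code{CanonicalElement}
#' @export
canonicalElement <- function(family, sequence, ltrLengthBp,
                             internalStart = ltrLengthBp + 1L,
                             internalEnd = length(sequence) - ltrLengthBp,
                             sourceLocus = "") {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  new("CanonicalElement", family = family, sequence = sequence,
      ltrLengthBp = as.integer(ltrLengthBp),
      internalStart = as.integer(internalStart),
      internalEnd = as.integer(internalEnd), sourceLocus = sourceLocus)
}

#' @rdname CanonicalElement-accessors
#' @export
setMethod("canonicalSequence", "CanonicalElement", function(object) object@sequence)

#' @rdname CanonicalElement-accessors
#' @export
setMethod("ltrLength", "CanonicalElement", function(object) object@ltrLengthBp)

#' @rdname CanonicalElement-accessors
#' @export
setMethod("internalRegion", "CanonicalElement",
          function(object) c(start = object@internalStart, end = object@internalEnd))

#' @rdname CanonicalElement-accessors
#' @export
setMethod("teFamily", "CanonicalElement", function(object) object@family)

setMethod("show", "CanonicalElement", function(object) {
  cat("CanonicalElement:", object@family, "\n")
  cat("  length:", length(object@sequence), "bp; LTR:", object@ltrLengthBp,
      "bp; internal:", object@internalStart, "-", object@internalEnd, "\n")
  if (nzchar(object@sourceLocus)) cat("  source:", object@sourceLocus, "\n")
})

## ---------------------------------------------------------------------------
## Codon alignments and dN/dS estimates
## ---------------------------------------------------------------------------

#' In-frame codon alignment of two coding sequences
#'
#' Two gap-free coding sequences of equal length divisible by 3, with no
#' internal stop codons.  The unit of analysis for \code{\link{ng86}} and
#' \code{\link{m0Pairwise}}.
#'
#' @slot seq1,seq2 the two sequences (character)
#' @slot labels length-2 labels
#' @export
setClass("CodonAlignment",
  representation(seq1 = "character", seq2 = "character", labels = "character")
)

setValidity("CodonAlignment", function(object) {
  msg <- character(0)
  n1 <- nchar(object@seq1); n2 <- nchar(object@seq2)
  if (n1 != n2) msg <- c(msg, "sequences must have equal length")
  if (n1 %% 3L != 0L || n1 < 3L)
    msg <- c(msg, "length must be a positive multiple of 3")
  if (grepl("-", object@seq1, fixed = TRUE) || grepl("-", object@seq2, fixed = TRUE))
    msg <- c(msg, "sequences must be gap-free")
  if (length(msg)) msg else TRUE
})

#' @param seq1,seq2 coding sequences (character or DNAString)
#' @param labels sequence labels
#' @rdname CodonAlignment-class
#' @return a validated \code{CodonAlignment}; an error names the codon index
#'   of any internal stop codon
#' @examples
#' codonAlignment("TTTGCTAAA", "TTCGCTAAA")
#' @export
codonAlignment <- function(seq1, seq2, labels = c("seq1", "seq2")) {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  obj <- new("CodonAlignment", seq1 = seq1, seq2 = seq2, labels = labels)
  for (s in c(1L, 2L)) {
    idx <- .stopCodonIndex(if (s == 1L) seq1 else seq2)
    if (length(idx))
      stop("internal stop codon in sequence ", s, " at codon index ", idx[1L])
  }
  obj
}

## ---------------------------------------------------------------------------

#' dN/dS estimate for one aligned coding pair
#'
#' @slot method "NG86" or "M0"
#' @slot dN,dS nonsynonymous and synonymous substitutions per site
#' @slot omega dN/dS (NA when dS is 0 or undefined)
#' @slot kappa transition/transversion ratio (M0 only, else NA)
#' @slot t fitted divergence, substitutions per codon (M0 only, else NA)
#' @slot nCodons number of codons used
#' @slot logLik maximized log-likelihood (M0 only, else NA)
#' @export
setClass("DnDsEstimate",
  representation(method = "character", dN = "numeric", dS = "numeric",
                 omega = "numeric", kappa = "numeric", t = "numeric",
                 nCodons = "integer", logLik = "numeric")
)

#' @rdname DnDsEstimate-accessors
#' @export
setMethod("dN", "DnDsEstimate", function(object) object@dN)

#' @rdname DnDsEstimate-accessors
#' @export
setMethod("dS", "DnDsEstimate", function(object) object@dS)

#' @rdname DnDsEstimate-accessors
#' @export
setMethod("omega", "DnDsEstimate", function(object) object@omega)

#' @rdname DnDsEstimate-accessors
#' @export
setMethod("kappa", "DnDsEstimate", function(object) object@kappa)

#' @rdname DnDsEstimate-accessors
#' @export
setMethod("branchLength", "DnDsEstimate", function(object) object@t)

setMethod("show", "DnDsEstimate", function(object) {
  cat(sprintf("DnDsEstimate (%s, %d codons): dN = %.4f, dS = %s, omega = %s\n",
              object@method, object@nCodons, object@dN,
              ifelse(is.na(object@dS), "NA", sprintf("%.4f", object@dS)),
              ifelse(is.na(object@omega), "NA", sprintf("%.4f", object@omega))))
})

## ---------------------------------------------------------------------------
## HTT evidence report
## ---------------------------------------------------------------------------

#' Consolidated horizontal-transfer evidence report
#'
#' Produced by \code{\link{runPipeline}}.  Collects, for one focal family,
#' the copy-number table, solo-LTR divergence summary, the TE-versus-host
#' synonymous divergence ratio test, the species-tree discordance test, the
#' Dollo loss count, breakpoint associations, and the per-line verdict.
#'
#' The three evidence lines mirror the classic HTT argument: (i)
#' unexpectedly high sequence similarity between species (dS ratio), (ii) a
#' patchy taxonomic distribution costly to explain by vertical inheritance
#' (Dollo losses), and (iii) discordance between element and species trees.
#'
#' @slot family focal family name
#' @slot copyNumbers per-strain copy-number table (data.frame)
#' @slot soloDivergence per-family solo-LTR divergence summary (data.frame)
#' @slot dsRatio result list from \code{\link{httDsTest}}
#' @slot discordance result list from \code{\link{discordanceTest}}
#' @slot dollo result list from \code{\link{dolloLossCount}}
#' @slot breakpoints breakpoint association table (data.frame; may be empty)
#' @slot lines named logical vector: which evidence lines fired
#' @export
setClass("HTTEvidenceReport",
  representation(family = "character", copyNumbers = "data.frame",
                 soloDivergence = "data.frame", dsRatio = "list",
                 discordance = "list", dollo = "list",
                 breakpoints = "data.frame", lines = "logical")
)

#' @rdname HTTEvidenceReport-accessors
#' @export
setMethod("evidenceLines", "HTTEvidenceReport", function(object) object@lines)

#' @rdname HTTEvidenceReport-accessors
#' @export
setMethod("verdict", "HTTEvidenceReport", function(object) any(object@lines))

setMethod("show", "HTTEvidenceReport", function(object) {
  cat("HTTEvidenceReport for family", object@family, "\n")
  ln <- object@lines
  for (nm in names(ln))
    cat(sprintf("  %-12s %s\n", nm, if (ln[[nm]]) "POSITIVE" else "negative"))
  cat("  overall:", if (any(ln)) "HTT supported" else "no HTT evidence", "\n")
})
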