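#' @include utils.R
NULL

#' Accessors for codon-model estimates
#'
#' \code{dN}, \code{dS}, \code{omega}, \code{kappa} and \code{branchLength}
#' extract the nonsynonymous rate, synonymous rate, their ratio, the
#' transition/transversion ratio and the fitted divergence from a
#' \linkS4class{DnDsEstimate}.
#'
#' @param object a \linkS4class{DnDsEstimate}
#' @return a numeric scalar (\code{NA} where the quantity is undefined for
#'   the estimator used)
#' @rdname DnDsEstimate-accessors
#' @export
setGeneric("dN", function(object) standardGeneric("dN"))

#' @rdname DnDsEstimate-accessors
#' @export
setGeneric("dS", function(object) standardGeneric("dS"))

#' @rdname DnDsEstimate-accessors
#' @export
setGeneric("omega", function(object) standardGeneric("omega"))

#' @rdname DnDsEstimate-accessors
#' @export
setGeneric("kappa", function(object) standardGeneric("kappa"))

#' @rdname DnDsEstimate-accessors
#' @export
setGeneric("branchLength", function(object) standardGeneric("branchLength"))

#' Accessors for canonical elements
#'
#' @param object a \linkS4class{CanonicalElement}
#' @return \code{canonicalSequence}: a \link[Biostrings]{DNAString};
#'   \code{ltrLength}: integer LTR length in bp; \code{internalRegion}:
#'   integer start/end (1-based, inclusive) of the internal region within the
#'   element; \code{teFamily}: the family name.
#' @rdname CanonicalElement-accessors
#' @export
setGeneric("canonicalSequence", function(object) standardGeneric("canonicalSequence"))

#' @rdname CanonicalElement-accessors
#' @export
setGeneric("ltrLength", function(object) standardGeneric("ltrLength"))

#' @rdname CanonicalElement-accessors
#' @export
setGeneric("internalRegion", function(object) standardGeneric("internalRegion"))

#' @rdname CanonicalElement-accessors
#' @export
setGeneric("teFamily", function(object) standardGeneric("teFamily"))

#' Accessors for HTT evidence reports
#'
#' \code{evidenceLines} returns the named logical vector of the three
#' evidence lines (similarity via dS ratio, patchy distribution via Dollo
#' loss counting, phylogenetic discordance); \code{verdict} returns a single
#' logical: whether any line supports horizontal transfer.
#'
#' @param object a \linkS4class{HTTEvidenceReport}
#' @rdname HTTEvidenceReport-accessors
#' @export
setGeneric("evidenceLines", function(object) standardGeneric("evidenceLines"))

#' @rdname HTTEvidenceReport-accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
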