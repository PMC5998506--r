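## Codon-level evolutionary statistics: NG86 counting estimator, pairwise
## M0 (GY94-style) maximum-likelihood estimator, host dS baseline, and the
## TE-vs-host dS ratio test for horizontal transfer.
##
## Standard genetic code only; the state space is the 61 sense codons.

#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Static codon tables (standard code)
## ---------------------------------------------------------------------------

.codonData <- local({
  bases <- c("A", "C", "G", "T")
  codons64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ## outer() above builds pos1 fastest; rebuild in lexicographic order
  codons64 <- sort(codons64)
  gc <- Biostrings::GENETIC_CODE[codons64]
  sense <- codons64[gc != "*"]
  aa <- unname(gc[gc != "*"])
  n <- length(sense)                      # 61
  codonMat <- do.call(rbind, strsplit(sense, ""))
  ntIdx <- matrix(match(codonMat, bases), nrow = n)   # n x 3 base indices

  ## single-substitution neighbor pairs among sense codons
  pairs <- list(); np <- 0L
  isTransition <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diffs <- which(codonMat[i, ] != codonMat[j, ])
      if (length(diffs) == 1L) {
        np <- np + 1L
        pairs[[np]] <- c(i, j, diffs,
                         as.integer(isTransition(codonMat[i, diffs], codonMat[j, diffs])),
                         as.integer(aa[i] == aa[j]))
      }
    }
  }
  nb <- do.call(rbind, pairs)
  colnames(nb) <- c("i", "j", "pos", "ts", "syn")

  list(bases = bases, codons64 = codons64, gc = gc, sense = sense, aa = aa,
       ntIdx = ntIdx, neighbors = nb)
})

.stopCodonIndex <- function(seq) {
  v <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  which(.codonData$gc[v] == "*" & !is.na(.codonData$gc[v]))
}

.splitCodons <- function(seq) {
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

## ---------------------------------------------------------------------------
## NG86
## ---------------------------------------------------------------------------

## Synonymous site count of one codon: per position, each of the three
## single-nucleotide changes contributes 1/3 if it is synonymous; changes to
## stop codons are skipped (they contribute to the nonsynonymous remainder
## N = 3 - S).
.ng86Sites <- local({
  cd <- .codonData
  s <- setNames(numeric(length(cd$sense)), cd$sense)
  for (idx in seq_along(cd$sense)) {
    codon <- cd$sense[idx]
    cnt <- 0
    for (pos in 1:3) {
      for (b in cd$bases) {
        if (b == substr(codon, pos, pos)) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (cd$gc[mut] == "*") next
        if (cd$gc[mut] == cd$aa[idx]) cnt <- cnt + 1 / 3
      }
    }
    s[idx] <- cnt
  }
  s
})

## Pathway-averaged synonymous/nonsynonymous difference counts for one codon
## pair.  Pathways through stop codons are excluded; if every pathway is
## blocked, all pathways are used with steps to/from stops counted as
## nonsynonymous.
.ng86Diff <- function(c1, c2) {
  gc <- .codonData$gc
  diffs <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(diffs)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
    `1` = list(diffs),
    `2` = list(diffs, rev(diffs)),
    `3` = {
      p <- list()
      for (a in 1:3) for (b in 1:3) for (cc in 1:3)
        if (length(unique(c(a, b, cc))) == 3L)
          p[[length(p) + 1L]] <- diffs[c(a, b, cc)]
      p
    })
  evalPath <- function(path, allowStops) {
    cur <- c1; sd <- 0; ndf <- 0
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[nxt] == "*" && !allowStops) return(NULL)
      if (gc[nxt] != "*" && gc[cur] != "*" && gc[nxt] == gc[cur]) {
        sd <- sd + 1
      } else {
        ndf <- ndf + 1
      }
      cur <- nxt
    }
    c(sd, ndf)
  }
  res <- Filter(Negate(is.null), lapply(perms, evalPath, allowStops = FALSE))
  if (!length(res)) res <- lapply(perms, evalPath, allowStops = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1L]), nd = mean(m[, 2L]))
}

#' NG86 counting estimate of dN and dS
#'
#' Nei-Gojobori (1986) estimator for one in-frame pair: synonymous and
#' nonsynonymous sites are counted per codon (averaged over the two
#' sequences), differences are counted with equal weighting over
#' substitution pathways (pathways through stop codons excluded), and the
#' proportions are corrected for multiple hits with the Jukes-Cantor
#' formula.
#'
#' \code{dS} is \code{NA} when the synonymous proportion reaches the
#' correction domain boundary (pS >= 3/4), and \code{omega} is \code{NA}
#' when \code{dS} is 0 or undefined.
#'
#' @param pair a \linkS4class{CodonAlignment}
#' @return a \linkS4class{DnDsEstimate} with \code{method = "NG86"}
#' @examples
#' est <- ng86(codonAlignment("TTTGCTAAA", "TTCGCTAAA"))
#' dS(est)   # -(3/4) * log(0.2) = 1.207
#' @export
ng86 <- function(pair) {
  stopifnot(is(pair, "CodonAlignment"))
  cod1 <- .splitCodons(pair@seq1)
  cod2 <- .splitCodons(pair@seq2)
  keep <- !is.na(.codonData$gc[cod1]) & !is.na(.codonData$gc[cod2]) &
    .codonData$gc[cod1] != "*" & .codonData$gc[cod2] != "*"
  cod1 <- cod1[keep]; cod2 <- cod2[keep]
  L <- length(cod1)
  S <- (sum(.ng86Sites[cod1]) + sum(.ng86Sites[cod2])) / 2
  N <- 3 * L - S
  sd <- 0; ndf <- 0
  for (k in seq_len(L)) {
    if (cod1[k] == cod2[k]) next
    d <- .ng86Diff(cod1[k], cod2[k])
    sd <- sd + d[["sd"]]; ndf <- ndf + d[["nd"]]
  }
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) ndf / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    if (p <= 0) return(0)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)
  om <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  new("DnDsEstimate", method = "NG86", dN = dN, dS = dS, omega = om,
      kappa = NA_real_, t = NA_real_, nCodons = L, logLik = NA_real_)
}

## ---------------------------------------------------------------------------
## Pairwise M0 (GY94)
## ---------------------------------------------------------------------------

## F3x4 codon frequencies from the two sequences: position-specific
## nucleotide frequencies, floored and renormalized so every sense codon has
## positive frequency.
.f3x4 <- function(cod1, cod2) {
  cd <- .codonData
  m <- rbind(do.call(rbind, strsplit(cod1, "")), do.call(rbind, strsplit(cod2, "")))
  f <- sapply(1:3, function(p) {
    tab <- table(factor(m[, p], levels = cd$bases))
    pmax(as.numeric(tab) / sum(tab), 1e-4)
  })                                        # 4 x 3
  f <- sweep(f, 2, colSums(f), "/")
  pi <- f[cd$ntIdx[, 1L], 1L] * f[cd$ntIdx[, 2L], 2L] * f[cd$ntIdx[, 3L], 3L]
  pi / sum(pi)
}

## Rate matrix pieces for given (pi, kappa, omega); returns the symmetrized
## matrix, its scaling (expected substitutions per codon per unit time before
## normalization), and the synonymous fraction of total flux.
.m0Q <- function(pi, kap, om) {
  cd <- .codonData
  n <- length(pi)
  nb <- cd$neighbors
  rate <- ifelse(nb[, "ts"] == 1L, kap, 1) * ifelse(nb[, "syn"] == 1L, 1, om)
  Q <- matrix(0, n, n)
  Q[nb[, c("i", "j")]] <- pi[nb[, "j"]] * rate
  Q[nb[, c("j", "i")]] <- pi[nb[, "i"]] * rate
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))                 # mean rate per codon
  flux <- pi[nb[, "i"]] * pi[nb[, "j"]] * rate    # i->j and j->i flux halves
  rhoS <- 2 * sum(flux[nb[, "syn"] == 1L]) / mu
  list(Q = Q, mu = mu, rhoS = rhoS)
}

## Transition probabilities P(t) for the normalized chain via symmetric
## eigendecomposition (the chain is reversible).
.m0Eigen <- function(pi, kap, om) {
  qq <- .m0Q(pi, kap, om)
  Qn <- qq$Q / qq$mu
  sq <- sqrt(pi)
  B <- Qn * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sq, V = t(e$vectors * sq), lambda = e$values,
       rhoS = qq$rhoS)
}

.m0Prob <- function(eg, t) {
  P <- eg$U %*% (exp(eg$lambda * t) * eg$V)
  P[P < 1e-300] <- 1e-300
  P
}

## Observed codon-pair counts as index triplets into the sense-codon space.
.codonPairCounts <- function(cod1, cod2) {
  cd <- .codonData
  i <- match(cod1, cd$sense); j <- match(cod2, cd$sense)
  keep <- !is.na(i) & !is.na(j)
  key <- (i[keep] - 1L) * 61L + j[keep]
  tab <- table(key)
  key <- as.integer(names(tab))
  list(i = (key - 1L) %/% 61L + 1L, j = (key - 1L) %% 61L + 1L,
       n = as.numeric(tab), L = sum(keep))
}

.m0LogLik <- function(counts, pi, kap, om, t) {
  eg <- .m0Eigen(pi, kap, om)
  P <- .m0Prob(eg, t)
  sum(counts$n * log(pi[counts$i] * P[cbind(counts$i, counts$j)]))
}

#' Pairwise M0 (one-ratio) codon model fit
#'
#' Fits the Goldman-Yang one-ratio codon model to one in-frame pair by
#' maximum likelihood: a 61-state reversible Markov chain with
#' transition/transversion ratio kappa, nonsynonymous/synonymous rate ratio
#' omega, F3x4 codon frequencies estimated from the pair, and divergence t
#' (expected substitutions per codon).  The likelihood is maximized over
#' (t, kappa, omega) with a derivative-free search started from a small
#' parameter grid.
#'
#' dN and dS are derived from the fitted chain by the standard
#' site-normalized decomposition: with rhoS the synonymous fraction of the
#' substitution flux and rhoS1 its value at omega = 1 (the proportion of
#' synonymous mutational opportunity), \code{dS = t * rhoS / (3 * rhoS1)}
#' and \code{dN = t * (1 - rhoS) / (3 * (1 - rhoS1))}.
#'
#' @param pair a \linkS4class{CodonAlignment}; at least 30 codons are
#'   recommended (a warning is issued below that)
#' @param control list; \code{maxit} for the simplex search (default 500)
#'   and \code{reltol} (default 1e-10)
#' @return a \linkS4class{DnDsEstimate} with \code{method = "M0"}
#' @examples
#' pr <- simulateCodonPair(300, omega = 0.3, kappa = 2, t = 0.5, seed = 1)
#' m0Pairwise(pr)
#' @export
m0Pairwise <- function(pair, control = list()) {
  stopifnot(is(pair, "CodonAlignment"))
  maxit <- if (is.null(control$maxit)) 500L else control$maxit
  reltol <- if (is.null(control$reltol)) 1e-10 else control$reltol
  cod1 <- .splitCodons(pair@seq1)
  cod2 <- .splitCodons(pair@seq2)
  counts <- .codonPairCounts(cod1, cod2)
  if (counts$L < 30L)
    warning("fewer than 30 usable codons; M0 estimates will be noisy")
  if (counts$L == 0L) stop("no usable codons in pair")
  pi <- .f3x4(cod1, cod2)

  obj <- function(par) {
    t <- min(max(exp(par[1L]), 1e-9), 50)
    kap <- min(max(exp(par[2L]), 1e-4), 1e3)
    om <- min(max(exp(par[3L]), 1e-6), 1e3)
    -.m0LogLik(counts, pi, kap, om, t)
  }

  ## multistart grid, then full optimization from the two best grid points
  grid <- expand.grid(t = c(0.05, 0.5, 2), kap = c(1, 3), om = c(0.1, 0.5, 1.5))
  gv <- apply(grid, 1L, function(g) obj(log(as.numeric(g))))
  starts <- order(gv)[1:2]
  best <- NULL
  for (s in starts) {
    fit <- optim(log(as.numeric(grid[s, ])), obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0L && best$value > min(gv))
    stop("M0 optimizer failed to converge; last iterate: ",
         paste(signif(exp(best$par), 4), collapse = ", "))
  t <- min(max(exp(best$par[1L]), 1e-9), 50)
  kap <- exp(best$par[2L]); om <- exp(best$par[3L])

  rhoS <- .m0Q(pi, kap, om)$rhoS
  rhoS1 <- .m0Q(pi, kap, 1)$rhoS
  dS <- t * rhoS / (3 * rhoS1)
  dN <- t * (1 - rhoS) / (3 * (1 - rhoS1))
  omHat <- if (dS > 1e-12) dN / dS else NA_real_
  new("DnDsEstimate", method = "M0", dN = dN, dS = dS, omega = omHat,
      kappa = kap, t = t, nCodons = as.integer(counts$L),
      logLik = -best$value)
}

#' Expected dN and dS under the M0 model
#'
#' Closed-form expectations for given parameters, using the same
#' site-normalized decomposition as \code{\link{m0Pairwise}}.  Useful for
#' calibrating simulations (e.g. choosing t so that the expected dS is 1).
#'
#' @param omega,kappa,t M0 parameters (t in substitutions per codon)
#' @param pi codon frequencies over the 61 sense codons (default uniform)
#' @return named numeric vector with elements \code{dN} and \code{dS}
#' @export
m0ExpectedDnDs <- function(omega, kappa, t, pi = NULL) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  rhoS <- .m0Q(pi, kappa, omega)$rhoS
  rhoS1 <- .m0Q(pi, kappa, 1)$rhoS
  c(dN = t * (1 - rhoS) / (3 * (1 - rhoS1)), dS = t * rhoS / (3 * rhoS1))
}

## ---------------------------------------------------------------------------
## Host baseline and the dS ratio test
## ---------------------------------------------------------------------------

## Median defined as the lower of the two middle values for even n, so the
## reported baseline is always an observed dS value.
.lowerMedian <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Host-gene synonymous divergence baseline
#'
#' Fits M0 to each host CDS pair and summarizes the per-pair dS values.
#' The median is the lower of the two middle values for even n.
#'
#' @param cdsPairs list of \linkS4class{CodonAlignment}
#' @param control passed to \code{\link{m0Pairwise}}
#' @return list with \code{ds} (per-pair dS), \code{medianDs}, and
#'   \code{nAlignments}
#' @export
hostBaseline <- function(cdsPairs, control = list()) {
  stopifnot(length(cdsPairs) >= 1L)
  ds <- vapply(cdsPairs, function(p) {
    est <- tryCatch(m0Pairwise(p, control), error = function(e) NULL)
    if (is.null(est)) NA_real_ else dS(est)
  }, numeric(1))
  ds <- ds[!is.na(ds)]
  if (!length(ds)) stop("every host CDS pair failed M0 fitting")
  list(ds = ds, medianDs = .lowerMedian(ds), nAlignments = length(ds))
}

#' TE-versus-host dS ratio test for horizontal transfer
#'
#' A transposable element inherited vertically accumulates synonymous
#' divergence at the same clock as host genes, so its dS between two species
#' should match the host-gene baseline.  A dS far below the host median
#' indicates the element moved between the species more recently than they
#' diverged.  The statistic is the ratio of the host median dS to the mean
#' TE dS; ratios at or above \code{ratioThreshold} flag HTT.
#'
#' @param teEstimates list of \linkS4class{DnDsEstimate} for TE coding
#'   segments (e.g. GAG and POL)
#' @param baseline result of \code{\link{hostBaseline}}
#' @param ratioThreshold flagging threshold (default 2)
#' @return list with \code{teDs} (mean TE dS), \code{hostMedianDs},
#'   \code{ratio}, \code{flagged} and \code{ratioThreshold}
#' @export
httDsTest <- function(teEstimates, baseline, ratioThreshold = 2) {
  stopifnot(length(teEstimates) >= 1L)
  teDs <- mean(vapply(teEstimates, dS, numeric(1)))
  if (is.na(teDs)) stop("TE dS undefined")
  ratio <- if (teDs == 0) Inf else baseline$medianDs / teDs
  list(teDs = teDs, hostMedianDs = baseline$medianDs, ratio = ratio,
       flagged = ratio >= ratioThreshold, ratioThreshold = ratioThreshold)
}

#' Drop stop-containing codon columns from a coding pair
#'
#' Utility for coding pairs extracted from genomic annotations, where
#' nucleotide-level divergence can have introduced stop codons: removes
#' every codon column in which either sequence has a stop or an ambiguous
#' base, then builds a \linkS4class{CodonAlignment}.
#'
#' @param seq1,seq2 equal-length in-frame sequences (character or DNAString)
#' @param labels passed through
#' @return a \linkS4class{CodonAlignment}
#' @export
maskStopCodons <- function(seq1, seq2, labels = c("seq1", "seq2")) {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  n <- min(nchar(seq1), nchar(seq2))
  n <- n - n %% 3L
  c1 <- .splitCodons(substr(seq1, 1L, n))
  c2 <- .splitCodons(substr(seq2, 1L, n))
  gc <- .codonData$gc
  keep <- !is.na(gc[c1]) & !is.na(gc[c2]) & gc[c1] != "*" & gc[c2] != "*"
  if (!any(keep)) stop("no stop-free codon columns left")
  codonAlignment(paste(c1[keep], collapse = ""), paste(c2[keep], collapse = ""),
                 labels = labels)
}
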