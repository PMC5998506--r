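---
title: "Detecting horizontal transposable element transfer with TEtransfer"
author: "TEtransfer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transposable element transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEtransfer)
```

## The problem

Transposable elements (TEs) normally descend vertically with their host
genomes, so a TE family's divergence between two species should mirror the
host divergence, its taxonomic distribution should be contiguous on the
species tree, and its phylogeny should recapitulate the species phylogeny.
Horizontal transposable element transfer (HTT) breaks all three
expectations at once. TEtransfer operationalizes this triad for
LTR retrotransposons in genome assemblies:

1. **Similarity**: synonymous divergence (dS) of the element's coding
   region between two species, compared with the genome-wide host-gene dS
   between the same species. Synonymous sites are near-neutral, so under
   vertical inheritance the two clocks agree; a TE dS far below the host
   median means the element crossed between the lineages recently. The
   test statistic is the ratio (host median dS) / (mean TE dS), flagged at
   a configurable threshold (default 2; clear transfers typically exceed
   4).
2. **Patchiness**: under Dollo parsimony (one gain, losses only), the
   minimum number of losses needed to explain the presence/absence
   pattern on the species tree, compared with the single event an HTT
   explanation needs. Two or more required losses count as evidence.
3. **Discordance**: the species composition of the sister group of the
   focal species' element clade, compared with the sister expected from
   the species tree. Disjoint sets flag discordance.

Each line is computable from assemblies alone; `runPipeline()` evaluates
all three and reports them in an `HTTEvidenceReport`.

## Annotation model

Copies are found by homology to a family library with separate LTR and
internal segments. The scanner is a seed-and-extend local matcher: exact
k-mer seeds (default k = 12) are grouped per diagonal, extended without
gaps under an x-drop rule (match +1, mismatch −2, drop-off 20), and
reduced to non-overlapping hits. k = 12 keeps seed density adequate down
to roughly 80% identity — the regime of the classic "80% coverage / 80%
identity" screen for nearly complete elements — while the mismatch
penalty terminates extension almost immediately in unrelated sequence.
There is no gapped alignment: the simulator evolves sequences without
indels, and for real data the merge step (below) absorbs the
fragmentation that indels cause.

Hits merge into copies per family: internal-segment hits cluster when
separated by at most `mergeGapBp` (default 500 bp, generous against
scanner fragmentation yet far below typical inter-copy distances); LTR
hits attach to the nearest internal cluster within the same gap (ties go
to the upstream cluster), and unattached LTR hits form solo-LTR copies.
Classification follows the canonical-coverage convention: *full-length*
requires both LTRs plus internal coverage strictly above 95% of the
canonical internal region, *truncated* means internal sequence below that
coverage, *solo LTR* means no internal match at all. Internal coverage is
the union of internal-segment query intervals divided by the canonical
internal length, so overlapping fragments are never double-counted.

## Structural detection and TSDs

Full-length elements are also detectable without a library: two similar
direct repeats (the LTRs) at a plausible element-scale separation
(defaults: LTR 100–1000 bp, element 4–15 kb, covering the ~6 kb elements
with ~300 bp LTRs typical of yeast *Ty4*-like families), flanked by a
target site duplication. The detector anchors shared k-mers at a common
separation, verifies the LTR pair by ungapped extension, and then searches
a ±6 bp window around the extended boundaries for an exact-length (5 bp by
default) duplication; when found, the boundaries snap to the TSD. This
matters because ungapped extension routinely overshoots a boundary by a
base or two whenever flanking sequence matches by chance; the TSD is the
only signal that pins the insertion site exactly.

tRNA association uses the edge-to-edge gap between element and tRNA gene
(0 when overlapping or abutting) against a ±1 kb window — measured from
boundaries, not midpoints, which is the conservative reading of that
convention.

## Canonical elements and activity dating

The canonical copy of a family is derived as in the classic workflow:
align the confirmed full-length copies (center-star progressive alignment
to the k-mer medoid — adequate for the low-divergence copies involved, not
a general aligner), take the majority consensus (columns with ≥ 50% gaps
dropped; base ties resolved lexicographically for determinism), and pick
the genomic copy with the smallest patristic distance to the consensus on
a p-distance neighbor-joining tree (ties resolved by genomic coordinate
order). Patristic rather than raw distance honors the "clusters most
closely in a tree" formulation.

Solo-LTR divergence to the canonical LTR dates family activity: solo LTRs
are recombination relics, so a family active long ago shows diverged solo
LTRs while a recent invader's are nearly identical. Divergences are plain
p-distances: at the values involved (≤ ~0.12) a substitution-model
correction would not change the second decimal, which is the reporting
precision.

## Codon models

`ng86()` is the standard Nei–Gojobori counting estimator: per-codon
synonymous site fractions (changes to stop codons skipped; the
nonsynonymous remainder is 3L − S), pathway-averaged difference counts
(pathways through stops excluded), and Jukes–Cantor correction. dS is
undefined (NA) at or beyond the correction's domain boundary pS ≥ 3/4.

`m0Pairwise()` fits the Goldman–Yang one-ratio model: a reversible
61-state codon chain with transition/transversion ratio κ, selection ratio
ω on nonsynonymous changes, F3x4 codon frequencies estimated from the
pair, and divergence t in substitutions per codon. The likelihood uses a
symmetric eigendecomposition of the rate matrix and is maximized over
(log t, log κ, log ω) by Nelder–Mead started from the two best points of a
3×2×3 parameter grid (t ∈ {0.05, 0.5, 2}, κ ∈ {1, 3}, ω ∈ {0.1, 0.5,
1.5}); convergence tolerance 1e-10 on the objective. dN and dS derive
from the fitted chain by the standard site-normalized decomposition, under
which the dN/dS ratio equals ω exactly. Below 30 codons the fit warns;
estimates there are noisy.

Coding pairs extracted from genomic annotations may contain stop codons
introduced by nucleotide-level divergence; `maskStopCodons()` removes the
affected codon columns before fitting. This trims a negligible fraction
of sites at the divergences where the dS test is informative.

The host baseline is the median of per-pair M0 dS values over host CDS
alignments, with the median defined as the lower of the two middle values
for even n so that the reported baseline is always an observed value.

## Phylogenetics

Neighbor joining uses the Studier–Keppler Q-criterion with ties broken by
the smallest index pair and negative branch-length estimates clamped to
zero (flagged via the tree's `"clamped"` attribute). On additive matrices
the implementation recovers the generating topology and branch lengths to
machine precision, which the test suite verifies against an independent
implementation. Bootstrap supports come from column resampling and
bipartition counting, reported as internal-node labels (the Newick
convention); midpoint rooting places the root halfway along the longest
leaf-to-leaf path.

Full maximum-likelihood tree search is deliberately out of scope: the
discordance and monophyly conclusions depend only on topology at the
divergences involved, which distance methods recover reliably; an
alignment column mask is available for excluding unreliable terminal
regions, mirroring common practice for element alignments.

The discordance test compares the observed sister-species set of the
focal clade in the element tree with the expected sister read from the
species tree, and by default prunes the species tree to the species
actually represented in the element tree. Without pruning, a species
whose copies simply failed to be sampled (or were never full-length)
masquerades as discordance; with it, the test only fires when the element
tree actively contradicts the species relationships among the species it
contains. A corollary worth knowing: if no species on the recipient's
side of the tree carries the family, a topological sister test cannot
detect the transfer — the similarity (dS) line carries the signal in that
situation.

Dollo loss counting places the single gain at the MRCA of carrier species
(any higher placement only adds lost subtrees) and counts maximal
carrier-free subtrees below it. The test suite checks this against an
independent dynamic program over all rooted topologies with up to six
leaves.

## Synteny and breakpoints

Whole-genome comparison uses MUM-style anchors: maximal runs of k-mers
(default k = 21) that occur exactly once in each genome, counting both
orientations — the one-to-one spirit of standard whole-genome-alignment
filtering. Anchors chain into co-linear blocks (gap cap 10 kb), blocks
below 2 kb are discarded (the conventional length filter), and adjacent
blocks on a query chromosome whose targets differ delimit an approximate
translocation breakpoint — an interval, not a point, matching how such
breakpoints can actually be localized. Breakpoints whose target pair is
swapped elsewhere are cross-referenced as reciprocal partners.

TE association reports copies overlapping the breakpoint interval
extended by a flank. The default flank is 0 (strict overlap); the
pipeline uses 1.5 kb because recently inserted, near-identical copies are
anchor deserts whose edges — unique junction-spanning k-mers — let blocks
reach to within a few bases of the junction, leaving the element just
outside the naked interval. The orientation-consistency flag records
whether the two associated elements share relative orientation, as
expected if a single ectopic exchange produced the translocation.

## The simulator

`simulateDataset()` generates the study conditions the workflow assumes:

* a species history (supplied Newick or a scaled random coalescent);
  host chromosomes evolve along it under per-site Jukes–Cantor with no
  indels — the simplest model that supports every downstream statistic;
* per family, a canonical element (LTR + stop-free coding internal region
  + LTR) whose per-species "master" evolves along the tree; copies are
  masters plus per-copy divergence drawn uniformly on [0, 2 × scale];
* copies in three states: full-length, 5'-truncated (a random 30–80%
  3'-fragment of the internal region plus the 3' LTR), or solo LTR
  (one LTR retaining the original TSD, mirroring LTR–LTR recombination);
* literal 5-bp TSDs: the host sequence at the insertion site is
  duplicated around the inserted copy. TSDs are host-derived and not
  further mutated — copies are modelled as young relative to flank
  turnover;
* tRNA genes placed ≥ 2 kb apart, with targeted insertions landing within
  ±150 bp of a tRNA and untargeted ones kept > 1.2 kb away, so the ±1 kb
  window flag has an unambiguous truth value;
* an optional HTT event: the recipient's master is re-derived from the
  donor lineage at the transfer time, giving recipient copies the low
  cross-species divergence and discordant tree position of a genuine
  transfer, plus a configurable post-transfer burst;
* optional reciprocal translocations applied after TE insertion, with
  full-length copies placed at the breakpoints on request (such copies
  are inserted divergence-free: fresh burst copies are what mediates
  ectopic exchange, and their identity is what makes real breakpoints
  anchor-free); plain junctions are kept ≥ 3 kb from any copy so the
  TE-association truth value is unambiguous;
* host CDS pairs between the donor and recipient lineages (or the two
  most distant species), evolved at the species-tree distance, for the
  host dS baseline.

Insertion sites keep a configurable minimum spacing (default 20 kb).
This is deliberately larger than the element-length search range so that
structural LTR-pair detection never pairs LTRs from different copies, and
it keeps truth-based evaluation well-posed; the cost is that simulated
genomes lack the tandem and nested insertions of real genomes.

What passing tests on simulated data do **not** show: robustness to
indels and assembly gaps (no indel process), to nested insertions, to
segmental duplications that violate anchor uniqueness, or to
misspecified libraries. The simulator is a correctness instrument for
the implemented statistics, not a realism benchmark.

## Reference study conditions

`httControlConfig()` fixes the validation conditions used throughout the
package's tests: six species on a fixed tree (two two-species clades and
a two-species outgroup clade; root-to-tip height 0.15 substitutions/site,
so cross-root species pairs sit at 0.3 — deep enough for an unambiguous
host baseline, shallow enough that a root-derived library still matches
all copies), genome 2 × 100 kb, one family (1.2 kb internal region,
insertion rate 60 per unit branch length, divergence scale 0.01, solo
and truncation probabilities 0.15 and 0.05). In the positive scenario
the family is native to the outgroup clade and to one species on the
other side of the tree — mirroring the common situation where distant
outgroup species carry old vertical copies — and transfers into sp2 at
divergence 0.02 with a burst of 8 copies; the negative control evolves
the same family vertically in all six species. Problem sizes throughout
the test suite (12 Mb for the classification benchmark, 10–20 seeds for
control replicates, 50 replicates for ω recovery) were chosen as the
smallest that make the corresponding checks statistically meaningful.

## Numerical and degenerate-input choices

* Codon frequencies are floored at 1e-4 per position-specific nucleotide
  before normalization, so unobserved codons cannot zero the likelihood.
* The M0 divergence t is clamped to [1e-9, 50]; identical pairs fit to
  the lower bound and report dN = dS = 0 within 1e-4.
* NJ Q-ties and consensus base ties are resolved deterministically
  (smallest index pair; lexicographic order).
* `pdistanceMatrix()` errors when a sequence pair shares no comparable
  columns rather than returning a silent NA.
* Zero-length trees midpoint-root arbitrarily with a warning and a flag.
* Solo-LTR copies aligning to less than half the canonical LTR are
  excluded from divergence summaries and counted as excluded.
* All randomness — simulation, bootstrap, pipeline — derives from a
  single integer seed, and reruns are byte-identical.

## Known limitations

* No indel handling anywhere in the alignment stack; real diverged copies
  with indels will fragment into multiple hits (the merge step absorbs
  this only partially).
* Nested insertions are split on family change only; full nested
  resolution is not attempted.
* The M0 implementation is pairwise-only (no site or branch models, no
  among-site rate variation, standard genetic code only).
* The discordance test is topological; rate-heterogeneity artifacts that
  can masquerade as discordance are not diagnosed.
* Breakpoint localization is interval-scale, not base-pair-scale.
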