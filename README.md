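# TEtransfer

Horizontal transfer of transposable elements (HTT) leaves three
characteristic footprints in genome assemblies: element copies in one
species that are far more similar to another species' copies than the host
genomes are to each other, a patchy taxonomic distribution that vertical
inheritance can only explain through repeated losses, and an element
phylogeny that contradicts the species phylogeny. TEtransfer implements a
complete desk-scale workflow for detecting HTT of LTR retrotransposons in
assembled genomes, modelled on the analysis style used for yeast *Ty*
elements, and ships a genome simulator with ground truth so that every
stage of the workflow can be validated end to end.

The package is aimed at researchers in molecular evolution and comparative
genomics who want a self-contained, scriptable version of this workflow —
annotation, structural detection, canonical-element derivation, codon-model
statistics, phylogenetics and synteny — without external binaries.

## What it computes

**Annotation and classification.** A seed-and-extend scanner
(`findHits()`) locates TE-homologous intervals against a library of
LTR/internal segments; `mergeAndClassify()` groups hits into copies and
classifies each as *full-length* (both LTRs and internal-region coverage
> 95% of the canonical internal region), *truncated* (internal coverage
below that), or *solo LTR* (no internal match). RepeatMasker `.out` files
can be used as the hit source (`readRepeatMaskerOut()`), and
`screenAssembly()` applies an 80/80-style coverage/identity screen.

**Structural detection.** `detectLTRCandidates()` finds full-length
elements de novo from direct-repeat (LTR) pairs, verifies pair identity,
and anchors boundaries on 5-bp target site duplications (TSDs);
`trnaProximity()` tests the ±1 kb tRNA-gene association typical of
*Ty4*-like integration.

**Canonical elements and dating.** `alignCopies()`, `consensusSequence()`
and `selectCanonical()` derive the canonical genomic copy as the one
closest to the family consensus in a neighbor-joining tree;
`soloLtrDivergence()` dates family activity from solo-LTR divergence to
the canonical LTR.

**Codon-model statistics.** `ng86()` implements the Nei–Gojobori counting
estimator; `m0Pairwise()` fits the Goldman–Yang one-ratio (M0) codon model
by maximum likelihood (61 sense codons, F3x4 frequencies, parameters ω, κ
and t). `hostBaseline()` and `httDsTest()` compare a TE's synonymous
divergence dS between two species against the host-gene median dS: under
vertical inheritance the ratio is near 1, while a recent transfer pushes it
far above (the test flags ratios ≥ 2 by default).

**Phylogenetics.** `neighborJoining()` (exact on additive matrices),
`bootstrapSupport()`, `midpointRoot()`, `monophylyAndSister()`,
`discordanceTest()` (element tree vs species tree), and
`dolloLossCount()` (minimum losses under single-gain Dollo parsimony vs a
single-transfer alternative).

**Synteny and rearrangements.** `findAnchors()` (unique exact matches),
`chainBlocks()`, `findBreakpoints()` (translocation breakpoints between
blocks with different target chromosomes), `associateTE()` (full-length
elements at both breakpoints of a reciprocal translocation, with
orientation consistency), and `assignSubgenome()` for hybrid scaffolds.

**Simulation and orchestration.** `simulateDataset()` generates
multi-species assemblies with planted TE copies in all three states, TSDs,
tRNA targeting, an optional HTT event with post-transfer burst, host CDS
pairs, and reciprocal translocations — all with a truth table.
`runPipeline()` runs the whole workflow and consolidates the three
evidence lines into an `HTTEvidenceReport`.

## Worked example

```r
library(TEtransfer)

## a positive-control dataset: six species, the focal family native to an
## outgroup clade, horizontally transferred into sp2 with a burst
report <- runPipeline(httControlConfig(1, positive = TRUE))
report
#> HTTEvidenceReport for family famH
#>   similarity   POSITIVE
#>   patchy       POSITIVE
#>   discordance  POSITIVE
#>   overall: HTT supported

report@dsRatio$ratio         # host median dS / TE dS
#> [1] 5.46
report@dollo$minLossesVertical
#> [1] 2
report@discordance$observedSister
#> [1] "sp5"
```

The dS ratio of 5.5 means the focal family's synonymous divergence between
recipient and donor is ~4.6 times lower than the host-gene baseline
between those species — the element moved long after the species split.
Two Dollo losses (against one transfer) say the presence/absence pattern
is costly to explain vertically, and the observed sister (`sp5`, the
donor) contradicts the species tree's expectation for `sp2`. The
vertical-inheritance control (`httControlConfig(1, positive = FALSE)`)
fires none of the three lines.

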