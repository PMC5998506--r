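Package: TEtransfer
Title: Detection of Horizontal Transposable Element Transfer in Genome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates and classifies LTR-retrotransposon copies in genome
    assemblies (full-length, truncated, solo LTR), detects full-length elements
    de novo from LTR pairs and target site duplications, derives canonical
    family elements by consensus and neighbor-joining, dates family activity
    via solo-LTR divergence, and tests for horizontal transposable element
    transfer (HTT) using three lines of evidence: transposon-versus-host
    synonymous divergence ratios under pairwise codon models (NG86 and
    Goldman-Yang M0), phylogenetic discordance between element and species
    trees, and Dollo loss counting for patchy presence/absence patterns.
    Anchor-based synteny comparison localizes translocation breakpoints and
    tests their association with full-length elements. A configurable genome
    simulator with ground-truth annotations supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer
Config/testthat/edition: 3
biocViews: Genetics, Annotation, Phylogenetics, SequenceMatching, Alignment
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'annotate.R'
    'phylo.R'
    'canonical.R'
    'codonevo.R'
    'synthdata.R'
    'synteny.R'
    'structure.R'
    'pipeline.R'
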