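Package: mitochar
Title: Mitochondrial Genome Architecture, Composition, Codon Usage and
    tRNA Structure Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes annotated circular mitochondrial genomes the way
    mitogenome announcement studies do: gene-architecture accounting on the
    circle (overlaps, intergenic spacers, exact adjacencies, strand
    inventory, per-class length totals), base composition with AT/GC skew
    for whole genomes and arbitrary regions, codon extraction from
    protein-coding genes under the vertebrate mitochondrial code including
    incomplete stop-codon typing, relative synonymous codon usage (RSCU),
    template-based tRNA cloverleaf folding with a per-arm wobble/mismatch
    census, and 13-gene supermatrix preparation with MrBayes NEXUS emission
    and clade-constraint assertions on resulting trees. A synthetic-genome
    generator with full planted ground truth makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, SequenceMatching, Annotation
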