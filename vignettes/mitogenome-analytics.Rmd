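---
title: "Characterizing annotated mitochondrial genomes with mitochar"
author: "mitochar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing annotated mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## What this package computes

Mitogenome announcement studies characterize a newly sequenced circular
mitochondrial genome along a standard battery: how tightly the 37 genes
are packed on the circle (overlaps, intergenic spacers, exact
adjacencies, strand inventory, per-class length totals), what the base
composition and its strand asymmetries look like (A+T content, AT skew,
GC skew), how the 13 protein-coding genes (PCGs) use codons (start/stop
typing including incomplete stops, relative synonymous codon usage), and
whether the 22 tRNAs fold into canonical cloverleafs and with how many
wobble pairs.  Finally the PCGs are concatenated into a supermatrix for
Bayesian phylogenetic inference.  `mitochar` implements that battery as
a tested pipeline that runs entirely offline: the worked reference
throughout is the blue whistling thrush (*Myophonus caeruleus*)
mitogenome, GenBank MN564936, whose published annotation and codon
counts ship with the package as plain-text tables under `inst/extdata`.

Annotation itself (gene finding, tRNA detection), read assembly,
sequence alignment and the MrBayes MCMC are deliberately out of scope:
annotated genomes are this package's *input*, and for phylogenetics it
emits inference-ready files and checks the resulting topology.

## Coordinates, gene names, and the two input modes

All coordinates are 1-based inclusive on the heavy-strand numbering,
matching how mitogenome feature tables are printed; strand is `H` or
`L`.  A feature spanning the circular origin is represented as two
sub-spans sharing a gene id — a span with `end > genome length` is never
allowed.  Published annotations mix naming conventions freely (ND5 /
NAD5 / nad5; COI / COX1 / cox1; OH / D-loop), so every reader funnels
names through one canonical vocabulary (`normalizeGeneName()`); unknown
names are kept and flagged, never dropped.

A genome may be a GenBank flat file with sequence, or a feature table
plus a declared length with *no sequence at all*.  The second
("feature-table-only") mode exists so that architecture and class-length
analytics can be run on a transcribed published table with zero
downloads; sequence-dependent operations refuse to run in that mode
rather than silently degrade.

The declared molecule length is authoritative even when it exceeds the
last annotated coordinate.  MN564936 is declared 16,815 bp while its
annotation ends at 16,518: the residual 297 bp is treated as
unannotated tail, and because the molecule is circular it becomes part
of the closing spacer between the control region and trnF.  The
published running text gives the largest interval as 296 bp and the
spacer total as 402 bp, one less than the coordinate arithmetic yields
(297 and 403); the package follows the arithmetic and reports the
discrepancy rather than adjusting either number.  Whether that tail is
control-region continuation or a pseudo-control region is not stated in
the record, so the package exposes it without guessing.

## Architecture accounting on the circle

```{r arch}
ft <- readFeatureTable(system.file("extdata", "MN564936_features.tsv",
                                   package = "mitochar"),
                       genome_length = 16815)
arch <- analyzeArchitecture(16815, ft, circular = TRUE)
arch
```

Genes are sorted by start (ties broken by end, then name) and every
consecutive pair on the circle — including the pair that closes through
the origin — is classified by the signed gap `next.start - prev.end - 1`:
negative is an overlap, zero an exact adjacency, positive a spacer.
Strand is ignored for pairing, since the published tables interleave H-
and L-strand genes in a single linear order.

Total overlap and spacer base pairs are computed by an *occupancy*
definition instead of summing the pairwise gaps: overlap bp is the
number of (position, extra-coverage) units — positions covered by *k*
genes contribute *k − 1* — and spacer bp is the number of positions
covered by no gene.  For ordinary annotations the two definitions
coincide; for nested or triply-overlapping features (absent from real
mitogenome tables but possible in fuzzed inputs) only the occupancy
definition keeps the conservation identity

> sum of gene lengths − overlap bp + spacer bp = genome length

exact, and that identity is asserted on every synthetic genome the test
suite generates.  Spacer fractions are reported against both the
declared genome length and the last annotated coordinate, labelled,
because published percentages are variously computed against either.

## Composition and skew

AT skew is `(A − T)/(A + T)` and GC skew `(G − C)/(G + C)`; both are
scale-invariant, so counts, proportions and percentages give identical
values, and the package exploits that to reproduce published skews from
printed percentages alone.  `N` bases are tallied separately and
excluded from skew denominators, keeping skews well-defined on draft
sequences.  Per-gene composition is computed on the coding (sense)
strand — published composition tables do not state the strand
convention for gene rows, so this assumption is documented here.  Full
precision is kept internally; report rounding (half-up, the convention
of printed tables, rather than R's round-half-even) happens only at the
formatting step, with percentages and skews at 2 decimals by default
and a precision argument where 3 decimals are wanted (published
whole-genome AT skew is quoted both as 0.118 and as 0.12; the package
treats these as one number at two precisions).

## Codon usage and incomplete stop codons

Stop typing and translation use the vertebrate mitochondrial code
(NCBI `transl_table=2`): complete stops are TAA, TAG, AGA, AGG.  A PCG
whose length is not a multiple of 3 must end in `TA` (typed `TA-`) or
`T` (typed `T--`) — incomplete stops completed to UAA by
post-transcriptional polyadenylation; any other remainder is flagged as
annotation-inconsistent.  In MN564936, nad1 ends `TA-` while cox3 and
nad4 end `T--` (nad4's length mod 3 is 1, which forces the single-base
form even though parts of the published text call it `TA*`).  Internal
stop codons raise a warning with their codon position rather than an
error, since provisional annotations are common.

RSCU for codon *c* in synonymous family *F* is
`count(c) × |F| / sum of counts over F`.  The family partition used for
reporting is the *standard-code* amino-acid grouping — leucine 6,
serine 6 (UCN + AGU/AGC), arginine 6 (CGN + AGA/AGG), the three
standard stops as one family, methionine and tryptophan singletons —
because that is the convention published mitogenome RSCU tables are
printed in: every triplet is tallied under its standard-code identity
(which is also why printed stop-family counts far exceed the number of
genes — mitochondrial AGA/AGG tryptophan-adjacent triplets inside genes
land in the standard stop and arginine families).  The MN564936 table
is reproduced to ±0.01 under exactly this partition and not under the
mitochondrial-code partition; both modes are available
(`codonFamilies("standard")`, `codonFamilies("mito")`), standard being
the default.  Families never observed get `NA` (reported blank), and
within every observed family mean RSCU is 1 by construction — the test
suite asserts this at 1e-9 on every run.

```{r rscu}
cu <- read.delim(system.file("extdata", "MN564936_codon_usage.tsv",
                             package = "mitochar"))
tab <- rscu(codonUsageTable(setNames(cu$count, cu$codon)))
head(codonUsageReport(tab)[order(-codonUsageReport(tab)$rscu), ], 3)
```

## tRNA cloverleaf folding

The folder is a constrained template search, not a wrapper around an
external predictor.  The cloverleaf is parameterized as consecutive
segments — acceptor 5' side, spacer (1–3 nt), DHU stem/loop, spacer
(0–2 nt), anticodon stem with a fixed 7-nt loop, variable loop
(3–23 nt), T-psi-C stem/loop, acceptor 3' side, 3' tail (0–5 nt) — with
stem sizes of 6–7 (acceptor), 3–4 (DHU), 4–5 (anticodon) and 4–5
(T-psi-C) pairs.  Every segment-length combination consistent with the
sequence length is enumerated exhaustively and scored +2 per
Watson–Crick pair, +1 per G–U wobble, −1 per anything else; the argmax
is returned.  Ties are broken deterministically: more stem pairs, then
a shorter variable loop, then the lexicographically smallest layout
tuple.  If the best layout has fewer than 15 positively-scoring pairs
the folder refuses with a "no cloverleaf" error — random sequence pairs
far below that bar, well-formed tRNAs far above it.  When the anticodon
is known it constrains the search to layouts that center it in the
anticodon loop.

The scoring weights and stem bounds are this package's own choices.
The published per-arm wobble census for MN564936 (24 G–U pairs: 8
acceptor, 6 DHU, 3 anticodon, 7 T-psi-C) was produced by a different
predictor whose exact stem boundaries are not printed, so the package
targets structural agreement on well-formed tRNAs rather than
replication of another tool's scores; the synthetic-data tests plant
known structures and require their recovery.  In reports all non-WC
pairs are counted as "mismatches" with G–U subclassed separately, since
published mitogenome texts call G–U pairs mismatches (sometimes
"mainly G–U", sometimes "all G–U" — the census reports both subclasses
and takes no side).

## Supermatrix preparation and topology assertions

`buildSupermatrix()` concatenates per-gene blocks in the canonical
13-PCG order (nad1, nad2, cox1, cox2, atp8, atp6, cox3, nad3, nad4l,
nad4, nad5, cob, nad6).  Input must be pre-aligned (equal per-gene
lengths across taxa) — alignment is an external step and the function
says so when lengths differ.  A taxon missing a gene is padded with the
missing symbol over that partition, and "remove the missing base parts"
is interpreted as column-wise deletion of any column containing a
missing symbol or gap in any taxon, controlled by a flag, with the
column accounting asserted exactly in tests.  `writeMrBayesNexus()`
emits the data, charset partitions and a `mrbayes` block whose defaults
encode a GTR+G+I run — `nst=6 rates=invgamma`, four chains, 400,000
generations, sampling every 100, 25% burn-in — all overridable.  The
MCMC itself is external by design; `assertTopology()` then checks a
nested clade expression such as
`"((((Monticola+Saxicola)+Oenanthe)+Phoenicurus)+Myophonus)"` against
the resulting tree, expanding genus names to their species leaves and
verifying each nested group is a clade.  One record-keeping note: the
GenBank entry HQ896033 is labelled *Cyanoptila cyanomelana* but is a
misidentified *Cyornis*; species relabelling like this is treated as
data (a label map supplied by the user), never hard-coded.

## The synthetic-genome generator

`generateMitoGenome()` turns a blueprint (`MitoGenomeSpec`) into a
genome whose every analyzable quantity is known in advance.  The
default blueprint (`templateMitoSpec()`) *is* the study condition: gene
order, strands, lengths, anticodons, inter-gene gaps, start/stop plans
(ATG starts, GTG for cox1, the TAA/TAG/AGA/AGG/TA-/T-- stop mix) and
whole-genome base composition (A 30.06, C 31.45, G 14.78, T 23.71%)
mirror the MN564936 record, codon weights default to its published
codon counts, and 24 wobble pairs are planted 8/6/3/7 across the four
arms of the 22 tRNAs.

Design points worth knowing:

* **Exact-count composition.** Non-coding sequence is a random
  *permutation* of a base multiset matching the target composition, not
  an i.i.d. sample, so a planted 60% A+T is recovered to rounding
  (±0.1% at any realistic length) rather than to sampling error.
* **Valid ORFs.** PCG bodies are sampled from the codon weights with
  the four mitochondrial stops excluded, then the planted start and
  (possibly incomplete) stop are written in, so every un-overlapped PCG
  is a clean ORF under the mitochondrial code.
* **Overlaps share sequence.** As in real mitogenomes, overlapping
  genes share bases; the later-written gene wins the shared span.  The
  TruthRecord therefore stores both the planted plans and quantities
  *measured on the final sequence* (base counts, skews, codon tallies,
  realized start/stops), plus per-feature `intact` flags; planted
  structure is guaranteed realized only for intact features, and tests
  that need clean plants use overlap-free blueprints.
* **Recovery is a 95% property for tRNA structure.** The exhaustive
  folder occasionally (empirically under 5% of cases) finds an
  alternative all-WC layout that legitimately outscores a planted
  wobble layout when random flanking bases happen to pair well; planted
  structural recovery is therefore asserted at the ≥95% level, while
  architecture, composition and codon tallies are asserted exactly.
* **Determinism.** One seeded RNG stream; the caller's RNG state is
  saved and restored.  The same seed yields byte-identical genomes,
  features and truth records.

`generateTaxa()` derives pre-aligned multi-taxon gene sets from a root
genome by i.i.d. substitutions (no indels), which is exactly enough to
exercise supermatrix construction; it makes no claim to realistic
evolutionary simulation (no codon models, no rate heterogeneity).

What passing tests on synthetic genomes do **not** show: real rRNA and
control-region sequence is highly structured, real tRNAs contain
modified bases and non-template deviations, and real annotations carry
boundary uncertainty.  The synthetic genomes validate the *accounting*
— that every analyzer recovers what was planted — not the biology.

## Test problem sizes and numerical conventions

The test suite runs on transcribed published tables (instant) and on
synthetic genomes of 2.5 kb with 10 genes for the seeded-recovery
sweeps (100 seeds), 16.8 kb for full-template checks, fuzzed circles of
up to 50 features for the occupancy-oracle comparisons, 100 synthetic
tRNAs for structure recovery, and random trees of up to 10 leaves for
the topology-assertion oracle; these sizes were chosen as the smallest
at which every property is non-trivially exercised.  Rounding in all
report outputs is half-up; all internal arithmetic is double precision
with integer base/codon counts.  Zero-length regions, empty feature
lists, homopolymer "tRNAs", 0-taxon matrices and origin-wrapping spans
on linear molecules are rejected with specific errors rather than
propagated.

## Known limitations

* The GenBank reader covers the flat-file dialect of mitogenome
  records (LOCUS, typed features with complement/join locations,
  gene/product/anticodon qualifiers, ORIGIN); it is not a general
  GenBank parser.
* The cloverleaf template does not model introns, non-canonical arm
  order, or armless mitochondrial tRNAs.
* RSCU is the only codon-usage statistic provided (no ENC, CAI or
  dN/dS).
* Sliding-window skew and origin-of-replication inference are out of
  scope.
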