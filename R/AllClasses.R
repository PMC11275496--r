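# S4 class definitions.  Accessors live next to the modules that own the
# objects; show() methods in show-methods.R.

#' CircularGenome: a (possibly sequence-less) circular mitogenome
#'
#' Holds an accession id, an optional nucleotide sequence over A/C/G/T/N,
#' the declared molecule length and the circular-topology flag.  The
#' declared length is authoritative (it may exceed the last annotated
#' coordinate); a genome may carry a length with no sequence at all
#' ("feature-table-only" mode), in which case sequence-dependent
#' operations refuse to run.
#'
#' @slot id accession string.
#' @slot seq character; the H-strand sequence, or `character(0)` when
#'   operating from a feature table alone.
#' @slot length integer; declared molecule length in bp.
#' @slot circular logical; circular topology flag.
#' @export
setClass("CircularGenome",
  representation(id = "character", seq = "character",
                 length = "integer", circular = "logical"))

setValidity("CircularGenome", function(object) {
  msg <- character(0)
  if (length(object@length) != 1L || is.na(object@length) || object@length <= 0L)
    msg <- c(msg, "declared length must be a single positive integer")
  if (length(object@seq) > 1L)
    msg <- c(msg, "seq must be a single string or absent")
  if (length(object@seq) == 1L) {
    if (nchar(object@seq) != object@length)
      msg <- c(msg, sprintf("sequence length (%d) != declared length (%d)",
                            nchar(object@seq), object@length))
    if (grepl("[^ACGTN]", object@seq))
      msg <- c(msg, "sequence contains characters outside A/C/G/T/N")
  }
  if (length(msg)) msg else TRUE
})

#' ArchitectureReport: circular gene-architecture accounting
#'
#' Result container of [analyzeArchitecture()]: every consecutive gene
#' pair on the circle is classified as an overlap, an intergenic spacer or
#' an exact adjacency; totals, the strand inventory and per-class length
#' summaries ride along.
#'
#' @slot overlaps data.frame (gene_a, gene_b, bp).
#' @slot spacers data.frame (gene_a, gene_b, bp).
#' @slot adjacencies data.frame (gene_a, gene_b).
#' @slot totals named numeric: overlap_bp, overlap_count, spacer_bp,
#'   spacer_count, adjacency_count.
#' @slot strandInventory list with `H` and `L` data.frames (gene, class).
#' @slot classLengths data.frame per feature class: total bp, fraction of
#'   genome, min/max gene.
#' @slot genomeLength integer.
#' @slot notes character; data-quality flags (nested features etc.).
#' @export
setClass("ArchitectureReport",
  representation(overlaps = "data.frame", spacers = "data.frame",
                 adjacencies = "data.frame", totals = "numeric",
                 strandInventory = "list", classLengths = "data.frame",
                 genomeLength = "integer", notes = "character"))

setValidity("ArchitectureReport", function(object) {
  msg <- character(0)
  t <- object@totals
  need <- c("overlap_bp", "overlap_count", "spacer_bp", "spacer_count",
            "adjacency_count")
  if (!all(need %in% names(t)))
    msg <- c(msg, "totals must contain overlap/spacer/adjacency fields")
  else {
    if (t[["overlap_count"]] != nrow(object@overlaps))
      msg <- c(msg, "overlap_count != number of overlap rows")
    if (t[["spacer_count"]] != nrow(object@spacers))
      msg <- c(msg, "spacer_count != number of spacer rows")
    if (t[["adjacency_count"]] != nrow(object@adjacencies))
      msg <- c(msg, "adjacency_count != number of adjacency rows")
    if (nrow(object@overlaps) && any(object@overlaps$bp < 1))
      msg <- c(msg, "overlap bp must be >= 1")
    if (nrow(object@spacers) && any(object@spacers$bp < 1))
      msg <- c(msg, "spacer bp must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' CodonUsageTable: per-codon counts, families and RSCU
#'
#' Codon counts aggregated over protein-coding genes plus the synonymous
#' family partition used to normalize them.  RSCU values are filled in by
#' [rscu()]; until then the slot holds `NA`.
#'
#' @slot counts named numeric over the 64 RNA codons (UUU..GGG).
#' @slot rscu named numeric, same codon order; NA until computed, and NA
#'   for families never observed.
#' @slot families named character mapping each codon to its family id.
#' @slot familyMode `"standard"` (standard-code amino-acid families, the
#'   convention mitogenome RSCU tables are printed in) or `"mito"`
#'   (vertebrate-mitochondrial-code families).
#' @export
setClass("CodonUsageTable",
  representation(counts = "numeric", rscu = "numeric",
                 families = "character", familyMode = "character"))

setValidity("CodonUsageTable", function(object) {
  msg <- character(0)
  if (length(object@counts) != 64L ||
      !identical(sort(names(object@counts)), sort(RNA_CODONS)))
    msg <- c(msg, "counts must be named over the 64 RNA codons")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (!identical(names(object@rscu), names(object@counts)))
    msg <- c(msg, "rscu must parallel counts")
  if (!all(names(object@counts) %in% names(object@families)))
    msg <- c(msg, "every codon needs a family assignment")
  if (length(msg)) msg else TRUE
})

#' CloverleafFold: one tRNA folded on the cloverleaf template
#'
#' Arm-resolved base-pair classification for a single tRNA: each stem pair
#' carries its 5'/3' positions and class (`WC`, `GU` wobble, `mismatch`),
#' grouped into the acceptor (amino-acid), DHU, anticodon and T-psi-C arms.
#'
#' @slot trna canonical tRNA id (or "" for anonymous sequences).
#' @slot pairs data.frame (arm, pos5, pos3, base5, base3, class).
#' @slot anticodonTriplet the 3-mer at the center of the anticodon loop.
#' @slot foldScore numeric template score of the chosen fold.
#' @slot layout named integer vector of template segment lengths.
#' @export
setClass("CloverleafFold",
  representation(trna = "character", pairs = "data.frame",
                 anticodonTriplet = "character", foldScore = "numeric",
                 layout = "integer"))

setValidity("CloverleafFold", function(object) {
  msg <- character(0)
  p <- object@pairs
  if (!all(c("arm", "pos5", "pos3", "class") %in% names(p)))
    msg <- c(msg, "pairs needs arm/pos5/pos3/class columns")
  else {
    if (anyDuplicated(c(p$pos5, p$pos3)))
      msg <- c(msg, "paired positions must be disjoint")
    if (!all(p$arm %in% c("acceptor", "DHU", "anticodon", "TPC")))
      msg <- c(msg, "unknown arm label")
    arms <- table(factor(p$arm, c("acceptor", "DHU", "anticodon", "TPC")))
    if (arms[["acceptor"]] > 7 || !(arms[["DHU"]] %in% 3:4) ||
        !(arms[["anticodon"]] %in% 4:5) || !(arms[["TPC"]] %in% 4:5))
      msg <- c(msg, "stem sizes outside cloverleaf bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Supermatrix: concatenated multi-gene alignment
#'
#' Per-taxon concatenation of equal-length (pre-aligned) gene blocks with
#' a partition table mapping genes to column ranges.  Taxa missing a gene
#' are padded with the missing-data symbol over that partition.
#'
#' @slot taxa ordered character vector of taxon labels.
#' @slot sequences named character; one concatenated row per taxon.
#' @slot partitions data.frame (gene, start, end), 1-based inclusive
#'   column spans tiling the matrix.
#' @slot missingChar single missing-data character (default `?`).
#' @export
setClass("Supermatrix",
  representation(taxa = "character", sequences = "character",
                 partitions = "data.frame", missingChar = "character"))

setValidity("Supermatrix", function(object) {
  msg <- character(0)
  if (length(object@taxa) == 0L) msg <- c(msg, "matrix must contain >= 1 taxon")
  if (!identical(names(object@sequences), object@taxa))
    msg <- c(msg, "sequences must be named by taxa, in order")
  w <- unique(nchar(object@sequences))
  if (length(w) > 1L) msg <- c(msg, "all rows must have equal length")
  p <- object@partitions
  if (nrow(p)) {
    if (p$start[1] != 1L || any(p$start[-1] != p$end[-nrow(p)] + 1L) ||
        p$end[nrow(p)] != w[1])
      msg <- c(msg, "partitions must tile [1, width] without overlap")
  }
  if (nchar(object@missingChar) != 1L)
    msg <- c(msg, "missingChar must be a single character")
  if (length(msg)) msg else TRUE
})

#' MitoGenomeSpec: blueprint for a synthetic circular mitogenome
#'
#' Fully determines a synthetic genome given a seed: gene order with
#' classes, strands, lengths and anticodons; signed inter-gene gaps
#' (negative = planted overlap, zero = exact adjacency, positive =
#' spacer); base composition for non-coding sequence; 64-codon sampling
#' weights for protein-coding genes; per-gene start/stop plans; and
#' planted G-U wobble pairs per tRNA arm.
#'
#' @slot genomeLength integer declared circle length.
#' @slot genes data.frame (gene, class, strand, length, anticodon,
#'   start_codon, stop_type).
#' @slot gaps integer vector of length `nrow(genes) - 1`; signed gap
#'   between consecutive genes (the circular closing gap is implied by
#'   genomeLength).
#' @slot baseFreqs named numeric A/C/G/T proportions summing to 1.
#' @slot codonWeights named numeric over 64 DNA codons; sampling weights
#'   for internal PCG codons (mito stop codons are excluded at sampling).
#' @slot trnaGU data.frame (gene, acceptor, DHU, anticodon, TPC) of
#'   planted wobble-pair counts.
#' @export
setClass("MitoGenomeSpec",
  representation(genomeLength = "integer", genes = "data.frame",
                 gaps = "integer", baseFreqs = "numeric",
                 codonWeights = "numeric", trnaGU = "data.frame"))

setValidity("MitoGenomeSpec", function(object) {
  msg <- character(0)
  g <- object@genes
  need <- c("gene", "class", "strand", "length", "anticodon",
            "start_codon", "stop_type")
  if (!all(need %in% names(g)))
    return(sprintf("genes must have columns: %s", paste(need, collapse = ", ")))
  if (length(object@gaps) != nrow(g) - 1L)
    msg <- c(msg, "gaps must have one entry per consecutive gene pair")
  if (abs(sum(object@baseFreqs) - 1) > 1e-6 ||
      !identical(sort(names(object@baseFreqs)), DNA_BASES))
    msg <- c(msg, "baseFreqs must be named A/C/G/T proportions summing to 1")
  lastEnd <- sum(g$length) + sum(object@gaps)
  closing <- object@genomeLength - lastEnd
  if (closing < 0)
    msg <- c(msg, sprintf(
      "genes + gaps (%d bp) exceed genomeLength (%d bp): plan inconsistent",
      lastEnd, object@genomeLength))
  pcg <- g[g$class == "PCG", ]
  if (nrow(pcg)) {
    rem <- pcg$length %% 3L
    bad <- (rem == 0L & !pcg$stop_type %in% c("TAA", "TAG", "AGA", "AGG")) |
           (rem == 2L & pcg$stop_type != "TA-") |
           (rem == 1L & pcg$stop_type != "T--")
    if (any(bad))
      msg <- c(msg, sprintf("stop plan inconsistent with gene length mod 3: %s",
                            paste(pcg$gene[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})
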