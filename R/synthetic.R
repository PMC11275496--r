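# Seeded synthetic circular mitogenomes with planted ground truth.
#
# A MitoGenomeSpec fixes gene order, classes, strands, lengths, signed
# inter-gene gaps (negative = overlap), base composition of non-coding
# sequence, codon-sampling weights for PCGs, start/stop plans and planted
# G-U wobble pairs per tRNA arm.  generate() is deterministic given a
# seed.  Non-coding sequence is an exact-count permutation of the target
# composition, so planted base frequencies are recovered to rounding, not
# just in expectation.
#
# Where planted genes overlap, the later-written gene overwrites the
# shared bases (as in real mitogenomes, overlapping genes share sequence);
# the TruthRecord therefore stores planted plans plus quantities measured
# on the final sequence, and flags which features remained intact.

#' Construct a synthetic-genome blueprint
#'
#' @param genome_length declared circle length (bp).
#' @param genes data.frame with columns `gene`, `class`, `strand`,
#'   `length`, and optionally `anticodon` (tRNAs), `start_codon` and
#'   `stop_type` (PCGs; stop must agree with `length %% 3`:
#'   complete TAA/TAG/AGA/AGG for 0, `TA-` for 2, `T--` for 1).
#' @param gaps signed integer gaps between consecutive genes (negative =
#'   overlap, 0 = adjacency, positive = spacer); the circular closing gap
#'   is implied by `genome_length`.
#' @param base_freqs named A/C/G/T proportions for non-coding sequence.
#' @param codon_weights sampling weights over the 64 DNA codons for
#'   internal PCG codons (mito stop codons are never sampled); default
#'   uniform over sense codons.
#' @param trna_gu data.frame (gene, acceptor, DHU, anticodon, TPC) of
#'   planted wobble-pair counts; default none.
#' @return a [MitoGenomeSpec-class].
#' @export
mitoGenomeSpec <- function(genome_length, genes, gaps,
                           base_freqs = c(A = .25, C = .25, G = .25, T = .25),
                           codon_weights = NULL, trna_gu = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"anticodon" %in% names(genes)) genes$anticodon <- NA_character_
  if (!"start_codon" %in% names(genes))
    genes$start_codon <- ifelse(genes$class == "PCG", "ATG", NA)
  if (!"stop_type" %in% names(genes))
    genes$stop_type <- ifelse(genes$class == "PCG",
      c("TAA", "T--", "TA-")[genes$length %% 3L + 1L], NA)
  if (is.null(codon_weights)) {
    codon_weights <- setNames(rep(1, 64), DNA_CODONS)
    codon_weights[MITO_STOPS] <- 0
  } else {
    nm <- gsub("U", "T", toupper(names(codon_weights)), fixed = TRUE)
    w <- setNames(numeric(64), DNA_CODONS)
    w[nm] <- as.numeric(codon_weights)
    codon_weights <- w
  }
  if (is.null(trna_gu))
    trna_gu <- data.frame(gene = character(0), acceptor = integer(0),
                          DHU = integer(0), anticodon = integer(0),
                          TPC = integer(0), stringsAsFactors = FALSE)
  # overlaps so deep that one gene swallows its neighbour are not a
  # pairwise architecture any more; refuse them up front
  ov <- -pmin(gaps, 0L)
  n <- nrow(genes)
  if (n > 1L && any(ov >= pmin(genes$length[-n], genes$length[-1])))
    .stopf("planted overlap as long as a flanking gene: spec inconsistent")
  new("MitoGenomeSpec", genomeLength = as.integer(genome_length),
      genes = genes, gaps = as.integer(gaps),
      baseFreqs = base_freqs[DNA_BASES],
      codonWeights = codon_weights, trnaGU = trna_gu)
}

#' Blueprint mirroring the published M. caeruleus annotation (MN564936)
#'
#' Gene order, strands, lengths, anticodons, inter-gene gaps, start/stop
#' plans and the whole-genome base composition default to the values of
#' the deposited 16,815 bp blue whistling thrush mitogenome; codon
#' weights default to its published codon counts, and 24 G-U wobble pairs
#' (8 acceptor, 6 DHU, 3 anticodon, 7 T-psi-C) are distributed over the
#' 22 tRNAs.
#'
#' @return a [MitoGenomeSpec-class].
#' @export
templateMitoSpec <- function() {
  ft <- readFeatureTable(system.file("extdata", "MN564936_features.tsv",
                                     package = "mitochar", mustWork = TRUE),
                         genome_length = 16815L)
  genes <- data.frame(gene = ft$gene, class = ft$class, strand = ft$strand,
                      length = featureLengths(ft), anticodon = ft$anticodon,
                      stringsAsFactors = FALSE)
  genes$start_codon <- ifelse(genes$class == "PCG",
                              ifelse(genes$gene == "cox1", "GTG", "ATG"), NA)
  genes$stop_type <- NA_character_
  ispcg <- genes$class == "PCG"
  stops <- c(nad1 = "TA-", nad2 = "TAA", cox1 = "AGG", cox2 = "TAA",
             atp8 = "TAA", atp6 = "TAA", cox3 = "T--", nad3 = "TAA",
             nad4l = "TAA", nad4 = "T--", nad5 = "AGA", cob = "TAA",
             nad6 = "TAG")
  genes$stop_type[ispcg] <- unname(stops[genes$gene[ispcg]])
  gaps <- ft$start[-1] - ft$end[-nrow(ft)] - 1L
  cu <- read.delim(system.file("extdata", "MN564936_codon_usage.tsv",
                               package = "mitochar", mustWork = TRUE),
                   stringsAsFactors = FALSE)
  weights <- setNames(cu$count, cu$codon)
  # planted wobble pairs: arm quota round-robined over the 22 tRNAs
  trnas <- genes$gene[genes$class == "tRNA"]
  armseq <- rep(c("acceptor", "DHU", "anticodon", "TPC"), c(8, 6, 3, 7))
  gu <- data.frame(gene = trnas, acceptor = 0L, DHU = 0L, anticodon = 0L,
                   TPC = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(armseq)) {
    tr <- ((i - 1L) %% length(trnas)) + 1L
    gu[tr, armseq[i]] <- gu[tr, armseq[i]] + 1L
  }
  mitoGenomeSpec(16815L, genes, gaps,
                 base_freqs = c(A = .3006, C = .3145, G = .1478, T = .2371),
                 codon_weights = weights, trna_gu = gu)
}

# exact-count random permutation achieving the target composition
.exactCompositionSeq <- function(n, freqs) {
  counts <- floor(freqs * n)
  rest <- n - sum(counts)
  if (rest > 0) {
    extra <- order(freqs * n - counts, decreasing = TRUE)[seq_len(rest)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(DNA_BASES, times = counts[DNA_BASES]))
}

#' Generate a synthetic tRNA gene on the cloverleaf template
#'
#' Builds a sequence of the requested length whose stems are fully
#' Watson-Crick paired except for the requested planted G-U wobble pairs,
#' with the anticodon centered in the anticodon loop.  Uses the current
#' RNG stream.
#'
#' @param length sequence length (nt).
#' @param anticodon 3-mer to center in the anticodon loop.
#' @param gu named integer vector of planted G-U pairs per arm
#'   (`acceptor`, `DHU`, `anticodon`, `TPC`).
#' @return the sequence (character) with attributes `layout` and
#'   `gu_planted`.
#' @export
syntheticTRNA <- function(length, anticodon = "GAA",
                          gu = c(acceptor = 0L, DHU = 0L,
                                 anticodon = 0L, TPC = 0L)) {
  lay <- .cloverleafLayouts(length)
  g <- lay$layouts
  if (!nrow(g)) .stopf("no cloverleaf layout fits %d nt", length)
  # prefer maximal stems (no extended-stem layout can then outscore the
  # planted one), then canonical spacer/loop sizes
  best <- order(-(g$a + g$d + g$c + g$t), abs(g$s1 - 2L), abs(g$tl - 7L),
                abs(g$dl - 6L), g$k, g$v)[1]
  pairs <- lay$pairs[lay$pairs$cid == best, , drop = FALSE]
  ch <- sample(DNA_BASES, length, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch[pairs$pos3] <- comp[ch[pairs$pos5]]
  for (arm in names(gu)) {
    k <- gu[[arm]]
    if (k == 0) next
    cand <- which(pairs$arm == arm)
    if (k > length(cand))
      .stopf("cannot plant %d G-U pairs on a %d-pair %s stem",
             k, length(cand), arm)
    for (ix in sample(cand, k)) {
      if (runif(1) < 0.5) { ch[pairs$pos5[ix]] <- "G"; ch[pairs$pos3[ix]] <- "T" }
      else                { ch[pairs$pos5[ix]] <- "T"; ch[pairs$pos3[ix]] <- "G" }
    }
  }
  at <- g$anticodon_at[best]
  ch[at + 0:2] <- .chars(gsub("U", "T", toupper(anticodon), fixed = TRUE))
  structure(paste(ch, collapse = ""),
            layout = g[best, ], gu_planted = gu)
}

# sample the internal codons of a PCG (never a mito stop codon)
.samplePcgCodons <- function(n, weights) {
  pool <- setdiff(DNA_CODONS, MITO_STOPS)
  w <- weights[pool]
  if (sum(w) <= 0) w <- rep(1, length(pool))
  sample(pool, n, replace = TRUE, prob = w / sum(w))
}

.pcgSequence <- function(len, start_codon, stop_type, weights) {
  rem <- len %% 3L
  ncod <- len %/% 3L
  complete_stop <- rem == 0L
  n_internal <- ncod - 1L - as.integer(complete_stop)
  if (n_internal < 0L) .stopf("PCG of %d bp too short", len)
  body <- c(start_codon, .samplePcgCodons(n_internal, weights))
  tailseq <- if (complete_stop) stop_type
             else if (rem == 2L) "TA" else "T"
  paste0(paste(body, collapse = ""), tailseq)
}

#' Generate a synthetic circular mitogenome with planted ground truth
#'
#' Deterministic given `seed`.  PCGs are valid open reading frames under
#' the vertebrate mitochondrial code with the planted start and stop
#' (complete or incomplete); tRNAs are cloverleaf templates with planted
#' wobble pairs; rRNA, control-region and intergenic sequence is an
#' exact-count permutation of the spec's base composition.
#'
#' @param spec a [MitoGenomeSpec-class].
#' @param seed integer RNG seed (recorded in the truth record).
#' @return list with `genome` ([CircularGenome-class]), `features`
#'   (feature data.frame) and `truth` (TruthRecord: planted plans plus
#'   quantities measured on the final sequence; see Details).
#' @details The TruthRecord contains: `seed`; measured base `counts`,
#'   `at_skew`, `gc_skew`; `architecture` totals implied by the planted
#'   gaps; the per-PCG `pcg` table (planted and realized start/stop); the
#'   planted per-arm wobble table `trna_gu`; measured `codon_counts`
#'   (sense triplets of all PCGs); and per-feature `intact` flags (TRUE
#'   when no later-written feature overwrote any of its bases, so planted
#'   structure is guaranteed realized).
#' @export
generateMitoGenome <- function(spec, seed = 1L) {
  stopifnot(is(spec, "MitoGenomeSpec"))
  validObject(spec)
  .withSeed(seed, {
    g <- spec@genes
    n <- nrow(g)
    starts <- integer(n); ends <- integer(n)
    starts[1] <- 1L; ends[1] <- g$length[1]
    if (n > 1L) for (i in 2:n) {
      starts[i] <- ends[i - 1L] + spec@gaps[i - 1L] + 1L
      ends[i] <- starts[i] + g$length[i] - 1L
    }
    L <- spec@genomeLength
    ch <- .exactCompositionSeq(L, spec@baseFreqs)
    # a feature stays intact unless a later-written sequence-bearing
    # feature (PCG or tRNA) overwrites part of its span
    writes <- g$class %in% c("PCG", "tRNA")
    intact <- rep(TRUE, n)
    for (i in seq_len(n)) {
      later <- which(writes & seq_len(n) > i)
      if (any(starts[later] <= ends[i] & ends[later] >= starts[i]))
        intact[i] <- FALSE
    }
    for (i in seq_len(n)) {
      sense <- switch(g$class[i],
        PCG = .pcgSequence(g$length[i], g$start_codon[i], g$stop_type[i],
                           spec@codonWeights),
        tRNA = {
          gu <- spec@trnaGU[spec@trnaGU$gene == g$gene[i], , drop = FALSE]
          guv <- if (nrow(gu))
            c(acceptor = gu$acceptor[1], DHU = gu$DHU[1],
              anticodon = gu$anticodon[1], TPC = gu$TPC[1])
          else c(acceptor = 0L, DHU = 0L, anticodon = 0L, TPC = 0L)
          as.character(syntheticTRNA(g$length[i],
            anticodon = if (is.na(g$anticodon[i])) "GAA" else g$anticodon[i],
            gu = guv))
        },
        NULL)                      # rRNA / control region: keep background
      if (!is.null(sense)) {
        hseq <- if (g$strand[i] == "L") revComp(sense) else sense
        ch[starts[i]:ends[i]] <- .chars(hseq)
      }
    }
    seqstr <- paste(ch, collapse = "")
    genome <- circularGenome(sprintf("synthetic-seed%d", seed), seqstr,
                             circular = TRUE)
    features <- geneFeatures(g$gene, g$strand, starts, ends, class = g$class,
                             anticodon = g$anticodon, genome_length = L,
                             normalize = FALSE)
    truth <- .truthRecord(spec, seed, ch, g, starts, ends, intact)
    list(genome = genome, features = features, truth = truth)
  })
}

.truthRecord <- function(spec, seed, ch, g, starts, ends, intact) {
  L <- spec@genomeLength
  counts <- table(factor(ch, levels = c(DNA_BASES, "N")))
  gaps <- c(spec@gaps, L - ends[nrow(g)] + starts[1] - 1L)
  pcg <- g[g$class == "PCG", , drop = FALSE]
  ix <- which(g$class == "PCG")
  codon_tally <- setNames(numeric(64), DNA_CODONS)
  realized_start <- realized_stop <- character(nrow(pcg))
  for (k in seq_along(ix)) {
    i <- ix[k]
    s <- paste(ch[starts[i]:ends[i]], collapse = "")
    if (g$strand[i] == "L") s <- revComp(s)
    ncod <- nchar(s) %/% 3L
    cods <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    tt <- table(factor(cods, levels = DNA_CODONS))
    codon_tally <- codon_tally + as.numeric(tt)
    realized_start[k] <- cods[1]
    rem <- nchar(s) %% 3L
    realized_stop[k] <- if (rem == 2L) paste0(substr(s, nchar(s) - 1L, nchar(s)), "-")
                        else if (rem == 1L) paste0(substr(s, nchar(s), nchar(s)), "--")
                        else cods[ncod]
  }
  list(
    seed = seed, genome_length = L,
    counts = setNames(as.numeric(counts), names(counts)),
    at_skew = atSkew(counts[["A"]], counts[["T"]]),
    gc_skew = gcSkew(counts[["G"]], counts[["C"]]),
    architecture = c(
      overlap_bp = sum(-gaps[gaps < 0]), overlap_count = sum(gaps < 0),
      spacer_bp = sum(gaps[gaps > 0]), spacer_count = sum(gaps > 0),
      adjacency_count = sum(gaps == 0)),
    pcg = data.frame(gene = pcg$gene,
                     planted_start = pcg$start_codon,
                     planted_stop = pcg$stop_type,
                     realized_start = realized_start,
                     realized_stop = realized_stop,
                     intact = intact[ix], stringsAsFactors = FALSE),
    trna_gu = spec@trnaGU,
    codon_counts = setNames(as.numeric(codon_tally), RNA_CODONS),
    intact = setNames(intact, g$gene))
}

#' Derive a set of taxa from a synthetic root genome
#'
#' Applies i.i.d. substitutions (no indels, so genes stay length-matched)
#' to the root's protein-coding genes, yielding pre-aligned per-gene
#' sequence sets ready for [buildSupermatrix()].
#'
#' @param spec a [MitoGenomeSpec-class] for the root genome.
#' @param n_taxa number of derived taxa.
#' @param per_site_sub_rate substitution probability per site, in
#'   `[0, 0.3]`.
#' @param seed RNG seed.
#' @param taxa optional taxon labels (default `taxon01`, ...).
#' @return list: `genes` (per gene, named character vector across taxa),
#'   `root` (the generated root, as from [generateMitoGenome()]), `rate`.
#' @export
generateTaxa <- function(spec, n_taxa, per_site_sub_rate, seed = 1L,
                         taxa = NULL) {
  if (per_site_sub_rate < 0 || per_site_sub_rate > 0.3)
    .stopf("per-site substitution rate must be in [0, 0.3]")
  root <- generateMitoGenome(spec, seed = seed)
  if (is.null(taxa)) taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa)
  pcgs <- root$features[root$features$class == "PCG", , drop = FALSE]
  .withSeed(seed + 1L, {
    genes <- list()
    for (i in seq_len(nrow(pcgs))) {
      sense <- genomeSpan(root$genome, pcgs$start[i], pcgs$end[i],
                          strand = pcgs$strand[i])
      base <- .chars(sense)
      out <- character(n_taxa)
      for (tx in seq_len(n_taxa)) {
        ch <- base
        hit <- which(runif(length(ch)) < per_site_sub_rate)
        for (h in hit) ch[h] <- sample(setdiff(DNA_BASES, ch[h]), 1L)
        out[tx] <- paste(ch, collapse = "")
      }
      genes[[pcgs$gene[i]]] <- setNames(out, taxa)
    }
    list(genes = genes, root = root, rate = per_site_sub_rate)
  })
}
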