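# Codon extraction from protein-coding genes under the vertebrate
# mitochondrial code (NCBI transl_table=2), incomplete stop-codon typing,
# codon counting and RSCU.
#
# Stop typing / translation use the mito code (complete stops TAA, TAG,
# AGA, AGG; a 1-bp T or 2-bp TA remainder is an incomplete stop completed
# by polyadenylation).  RSCU families, however, default to standard-code
# amino-acid groupings (Leu 6, Ser 6 = UCN+AGU/AGC, Arg 6 = CGN+AGA/AGG,
# stops {UAA, UAG, UGA}, Met and Trp singletons): that is the convention
# mitogenome RSCU tables are printed in, where every triplet is tallied
# under its standard-code identity.  A "mito" family mode is provided.

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Synonymous-family partition of the 64 codons
#'
#' @param mode `"standard"`: families by standard genetic code amino acid,
#'   with the three standard stops (UAA, UAG, UGA) forming one family.
#'   `"mito"`: families by vertebrate mitochondrial code (AUA is Met, UGA
#'   is Trp, AGA/AGG join the stop family).
#' @return named character vector mapping each RNA codon to a family id.
#' @export
codonFamilies <- function(mode = c("standard", "mito")) {
  mode <- match.arg(mode)
  code <- if (mode == "standard") Biostrings::getGeneticCode("1")
          else Biostrings::getGeneticCode("2")
  aa <- code[DNA_CODONS]
  setNames(unname(aa), RNA_CODONS)
}

#' Extract codons and start/stop typing from one protein-coding gene
#'
#' The sense-strand sequence (reverse complement for L-strand genes) is
#' split into triplets.  A remainder of 2 must read `TA` (incomplete stop
#' `TA-`), a remainder of 1 must be `T` (incomplete stop `T--`); a complete
#' terminal triplet is a stop only if it is one of TAA/TAG/AGA/AGG under
#' the vertebrate mitochondrial code.  Inconsistent remainders or a
#' non-stop terminal triplet are flagged, and internal stops raise a
#' warning with their codon position (annotations in progress are common).
#'
#' @param genome a [CircularGenome-class] with sequence.
#' @param feature one row of a feature data.frame with `class == "PCG"`
#'   (origin-split genes: both rows).
#' @return a `PcgCodonRecord`: list with `gene`, `start_codon`,
#'   `stop_codon` (3-mer, `"TA-"` or `"T--"`), `codons` (complete sense
#'   triplets, DNA alphabet, including a complete terminal stop),
#'   `n_codons` and `flags`.
#' @export
extractCodons <- function(genome, feature) {
  if (!all(feature$class == "PCG"))
    .stopf("extractCodons expects a PCG feature (got class '%s')",
           feature$class[1])
  feature <- feature[order(feature$part), , drop = FALSE]
  h <- paste0(mapply(function(s, e) genomeSpan(genome, s, e, strand = "H"),
                     feature$start, feature$end), collapse = "")
  s <- if (feature$strand[1] == "L") revComp(h) else h
  n <- nchar(s)
  rem <- n %% 3L
  ncod <- n %/% 3L
  codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  flags <- character(0)
  if (rem == 2L) {
    tailbases <- substr(s, n - 1L, n)
    if (tailbases == "TA") stop_codon <- "TA-"
    else { stop_codon <- NA_character_
           flags <- c(flags, sprintf("2-bp remainder '%s' is not TA", tailbases)) }
  } else if (rem == 1L) {
    tailbases <- substr(s, n, n)
    if (tailbases == "T") stop_codon <- "T--"
    else { stop_codon <- NA_character_
           flags <- c(flags, sprintf("1-bp remainder '%s' is not T", tailbases)) }
  } else {
    last <- codons[ncod]
    if (last %in% MITO_STOPS) stop_codon <- last
    else { stop_codon <- NA_character_
           flags <- c(flags, sprintf("terminal triplet %s is not a mito stop", last)) }
  }
  internal <- codons[seq_len(max(ncod - 1L, 0L))]
  isStop <- internal %in% MITO_STOPS & !grepl("N", internal)
  if (any(isStop)) {
    .warnf("%s: internal stop codon(s) at codon position(s) %s",
           feature$gene[1], paste(which(isStop), collapse = ", "))
    flags <- c(flags, sprintf("internal stops at %s",
                              paste(which(isStop), collapse = ",")))
  }
  if (length(flags) && is.na(stop_codon))
    .warnf("%s: annotation-inconsistent stop (%s)", feature$gene[1], flags[1])
  structure(list(gene = feature$gene[1], start_codon = codons[1],
                 stop_codon = stop_codon, codons = codons,
                 n_codons = ncod, flags = flags),
            class = "PcgCodonRecord")
}

#' Count codons across protein-coding genes
#'
#' Aggregates complete triplets over a set of `PcgCodonRecord`s into a
#' [CodonUsageTable-class].  Incomplete stops contribute nothing; codons
#' containing N are excluded and reported via a message.
#'
#' @param records list of records from [extractCodons()].
#' @param include_stops keep each gene's complete terminal stop triplet
#'   (default TRUE, the convention of published codon-usage tables).
#' @param family_mode passed to [codonFamilies()].
#' @return a [CodonUsageTable-class] with counts filled and RSCU unset.
#' @export
countCodons <- function(records, include_stops = TRUE,
                        family_mode = c("standard", "mito")) {
  if (!length(records)) .stopf("need at least one codon record")
  all_codons <- unlist(lapply(records, function(r) {
    cod <- r$codons
    if (!include_stops && length(cod) && !is.na(r$stop_codon) &&
        nchar(r$stop_codon) == 3L && cod[length(cod)] == r$stop_codon)
      cod <- cod[-length(cod)]
    cod
  }), use.names = FALSE)
  hasN <- grepl("N", all_codons, fixed = TRUE)
  if (any(hasN))
    message(sum(hasN), " codon(s) containing N excluded from counts")
  tab <- table(factor(all_codons[!hasN], levels = DNA_CODONS))
  counts <- setNames(as.numeric(tab), RNA_CODONS)
  codonUsageTable(counts, family_mode = match.arg(family_mode))
}

#' Build a CodonUsageTable from raw counts
#'
#' @param counts numeric vector of codon counts named by RNA or DNA
#'   codons (missing codons default to 0).
#' @param family_mode passed to [codonFamilies()].
#' @return a [CodonUsageTable-class] (RSCU unset; see [rscu()]).
#' @export
codonUsageTable <- function(counts, family_mode = c("standard", "mito")) {
  family_mode <- match.arg(family_mode)
  nm <- gsub("T", "U", toupper(names(counts)), fixed = TRUE)
  if (anyDuplicated(nm) || !all(nm %in% RNA_CODONS))
    .stopf("counts must be named by distinct codons")
  full <- setNames(numeric(64), RNA_CODONS)
  full[nm] <- as.numeric(counts)
  new("CodonUsageTable", counts = full,
      rscu = setNames(rep(NA_real_, 64), RNA_CODONS),
      families = codonFamilies(family_mode), familyMode = family_mode)
}

#' Relative synonymous codon usage
#'
#' For codon `c` in synonymous family `F`:
#' `RSCU(c) = count(c) * |F| / sum(count over F)` — the observed count
#' relative to expectation under uniform use within the family.  Families
#' with zero total are left `NA` (reported blank).
#'
#' @param table a [CodonUsageTable-class].
#' @return the table with the `rscu` slot filled.
#' @examples
#' leu <- c(UUA = 83, UUG = 38, CUU = 98, CUC = 128, CUA = 265, CUG = 66)
#' rscuValues(rscu(codonUsageTable(leu)))[["CUA"]]   # 2.345...
#' @export
rscu <- function(table) {
  stopifnot(is(table, "CodonUsageTable"))
  counts <- table@counts
  fam <- table@families
  out <- setNames(rep(NA_real_, 64), RNA_CODONS)
  for (f in unique(fam)) {
    cod <- names(fam)[fam == f]
    tot <- sum(counts[cod])
    if (tot > 0) out[cod] <- counts[cod] * length(cod) / tot
  }
  table@rscu <- out
  table
}

#' @describeIn rscu codon counts (named over the 64 RNA codons).
#' @export
codonCounts <- function(table) table@counts

#' @describeIn rscu RSCU values (NA until [rscu()] is applied).
#' @export
rscuValues <- function(table) table@rscu

#' Render a codon-usage table in report form
#'
#' @param table a [CodonUsageTable-class] (RSCU filled).
#' @param precision decimals for RSCU (half-up rounding, report style).
#' @return data.frame (codon, family, count, rscu) in TCAG codon order.
#' @export
codonUsageReport <- function(table, precision = 2) {
  data.frame(codon = RNA_CODONS,
             family = unname(table@families[RNA_CODONS]),
             count = unname(table@counts[RNA_CODONS]),
             rscu = roundHalfUp(unname(table@rscu[RNA_CODONS]), precision),
             stringsAsFactors = FALSE)
}
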