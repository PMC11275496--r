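# Base composition, A+T / G+C content and AT/GC skew for whole genomes
# and arbitrary (possibly origin-crossing) regions.
#
# Conventions: N bases are tallied separately and excluded from skew
# denominators, so skews stay well-defined on draft sequences.  Per-gene
# composition is computed on the coding (sense) strand.  Full precision is
# kept internally; rounding (half-up, report style) happens only when a
# precision is requested.

#' AT skew
#'
#' `(A - T) / (A + T)`.  Scale-invariant: counts, proportions and
#' percentages all give the same value.
#'
#' @param a_frac,t_frac A and T abundances on a common scale.
#' @return dimensionless skew in `[-1, 1]`.
#' @examples
#' atSkew(30.06, 23.71)   # 0.118 at 3 decimals
#' @export
atSkew <- function(a_frac, t_frac) {
  if (any(a_frac + t_frac <= 0))
    .stopf("AT skew undefined: A + T must be > 0")
  (a_frac - t_frac) / (a_frac + t_frac)
}

#' GC skew
#'
#' `(G - C) / (G + C)`; see [atSkew()].
#'
#' @param g_frac,c_frac G and C abundances on a common scale.
#' @return dimensionless skew in `[-1, 1]`.
#' @examples
#' gcSkew(14.78, 31.45)   # -0.36 at 2 decimals
#' @export
gcSkew <- function(g_frac, c_frac) {
  if (any(g_frac + c_frac <= 0))
    .stopf("GC skew undefined: G + C must be > 0")
  (g_frac - c_frac) / (g_frac + c_frac)
}

#' Base composition of a genome or region
#'
#' @param genome a [CircularGenome-class] with sequence (errors in
#'   feature-table-only mode).
#' @param start,end optional 1-based inclusive span; whole genome when
#'   omitted.  `start > end` wraps through the origin on circular genomes.
#' @param strand `"H"` (default) or `"L"`; the L reading is the reverse
#'   complement of the span.
#' @param region_id label for the output row.
#' @return one-row data.frame: region, counts (`a,c,g,t,n`), percentages
#'   (`a_pct..n_pct`, of all bases), `at_pct`, `gc_pct` (of non-N bases),
#'   `at_skew`, `gc_skew`.
#' @examples
#' composition(circularGenome("toy", "ACGT"))
#' @export
composition <- function(genome, start = NULL, end = NULL, strand = "H",
                        region_id = NULL) {
  if (!hasSequence(genome))
    .stopf("genome '%s' is in feature-table-only mode: composition needs a sequence",
           genomeID(genome))
  whole <- is.null(start) && is.null(end)
  if (whole) { start <- 1L; end <- genomeLength(genome) }
  if (is.null(region_id))
    region_id <- if (whole) "whole_genome" else sprintf("%d-%d", start, end)
  s <- genomeSpan(genome, start, end, strand = strand)
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s), baseOnly = TRUE)
  cnt <- c(a = unname(f["A"]), c = unname(f["C"]),
           g = unname(f["G"]), t = unname(f["T"]), n = unname(f["other"]))
  tot <- sum(cnt)
  acgt <- tot - cnt[["n"]]
  if (acgt == 0) .stopf("region '%s' contains no A/C/G/T bases", region_id)
  pct <- 100 * cnt / tot
  data.frame(
    region = region_id,
    a = cnt[["a"]], c = cnt[["c"]], g = cnt[["g"]], t = cnt[["t"]],
    n = cnt[["n"]],
    a_pct = pct[["a"]], c_pct = pct[["c"]], g_pct = pct[["g"]],
    t_pct = pct[["t"]], n_pct = pct[["n"]],
    at_pct = 100 * (cnt[["a"]] + cnt[["t"]]) / acgt,
    gc_pct = 100 * (cnt[["g"]] + cnt[["c"]]) / acgt,
    at_skew = atSkew(cnt[["a"]], cnt[["t"]]),
    gc_skew = gcSkew(cnt[["g"]], cnt[["c"]]),
    stringsAsFactors = FALSE)
}

#' Composition/skew table over named regions
#'
#' One row per requested region plus the whole genome, mirroring how
#' mitogenome studies print their composition tables.  Gene regions are
#' read on the coding (sense) strand.
#'
#' @param genome a [CircularGenome-class] with sequence.
#' @param features feature data.frame used to resolve region names.
#' @param regions character vector of gene ids (canonical or aliases); the
#'   whole genome is always included first.
#' @param precision optional integer; when given, percentages and skews
#'   are rounded half-up to that many decimals for reporting.
#' @return data.frame of composition rows.
#' @export
regionReport <- function(genome, features, regions = NULL, precision = NULL) {
  rows <- list(composition(genome))
  regions <- setdiff(regions %||% character(0), c("whole_genome", "whole"))
  for (r in regions) {
    g <- normalizeGeneName(r)
    hit <- features[features$gene == g, , drop = FALSE]
    if (!nrow(hit))
      .stopf("region '%s' not found in the feature table", r)
    if (any(featureLengths(hit) < 1L))
      .stopf("region '%s' has a zero-length span", r)
    if (nrow(hit) == 1L) {
      rows[[length(rows) + 1L]] <-
        composition(genome, hit$start, hit$end, strand = hit$strand[1],
                    region_id = g)
    } else {  # origin-split feature: wrap through the origin
      hit <- hit[order(hit$part), ]
      rows[[length(rows) + 1L]] <-
        composition(genome, hit$start[1], hit$end[nrow(hit)],
                    strand = hit$strand[1], region_id = g)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(precision)) {
    num <- c("a_pct", "c_pct", "g_pct", "t_pct", "n_pct", "at_pct",
             "gc_pct", "at_skew", "gc_skew")
    out[num] <- lapply(out[num], roundHalfUp, d = precision)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
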