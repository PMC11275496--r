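# Gene features travel as a validated data.frame with 1-based inclusive
# coordinates on the H-strand numbering and strand in {H, L}.  Features
# spanning the circular origin are represented as two sub-spans sharing a
# gene id ('part' column), never as end > genome length.

#' Construct a validated gene-feature table
#'
#' @param gene character; gene names (normalized through
#'   [normalizeGeneName()] unless `normalize = FALSE`).
#' @param strand character in `{H, L}`.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param class optional feature class; inferred from the canonical
#'   vocabulary when missing.
#' @param anticodon optional 3-mer for tRNAs.
#' @param genome_length optional; when given, spans are checked against it.
#' @param normalize map names through the canonical alias table.
#' @return data.frame with columns gene, class, strand, start, end,
#'   anticodon, part, sorted by start (ties: end, then gene).
#' @examples
#' geneFeatures("trnF", "H", 1, 68, anticodon = "GAA")
#' @export
geneFeatures <- function(gene, strand, start, end, class = NULL,
                         anticodon = NA_character_, genome_length = NULL,
                         normalize = TRUE) {
  n <- length(gene)
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    .stopf("start/end must be integral")
  if (any(start < 1L)) .stopf("coordinates are 1-based: start >= 1 required")
  if (any(start > end))
    .stopf("start > end for feature(s): %s",
           paste(gene[start > end], collapse = ", "))
  if (!all(strand %in% c("H", "L")))
    .stopf("strand must be 'H' or 'L' (got: %s)",
           paste(unique(setdiff(strand, c("H", "L"))), collapse = ", "))
  if (normalize) {
    gene <- normalizeGeneName(gene)
    if (any(attr(gene, "unmapped")))
      .warnf("unmapped gene name(s) retained as-is: %s",
             paste(unique(gene[attr(gene, "unmapped")]), collapse = ", "))
  }
  if (is.null(class)) class <- .classOf(gene)
  anticodon <- rep_len(toupper(as.character(anticodon)), n)
  anticodon[anticodon %in% c("", "-", "NA")] <- NA_character_
  bad_ac <- !is.na(anticodon) & class != "tRNA"
  if (any(bad_ac))
    .stopf("anticodon given for non-tRNA feature(s): %s",
           paste(gene[bad_ac], collapse = ", "))
  df <- data.frame(gene = as.character(gene), class = class,
                   strand = strand, start = start, end = end,
                   anticodon = anticodon,
                   part = rep(1L, n), stringsAsFactors = FALSE)
  if (!is.null(genome_length) && any(df$end > genome_length))
    .stopf("feature(s) extend past genome length %d: %s", genome_length,
           paste(df$gene[df$end > genome_length], collapse = ", "))
  dup <- df$gene[duplicated(df$gene) & df$part == 1L]
  dup <- setdiff(dup, df$gene[attrUnmapped(gene)])
  if (length(dup)) {
    spans <- vapply(dup, function(g) {
      r <- df[df$gene == g, ]
      paste(sprintf("%d-%d", r$start, r$end), collapse = " and ")
    }, "")
    .stopf("duplicate canonical gene id(s): %s",
           paste(sprintf("%s (%s)", dup, spans), collapse = "; "))
  }
  sortFeatures(df)
}

attrUnmapped <- function(gene) {
  u <- attr(gene, "unmapped")
  if (is.null(u)) rep(FALSE, length(gene)) else u
}

#' Sort a feature table by start (stable; ties by end, then gene)
#' @param features a feature data.frame.
#' @return the sorted data.frame, row names reset.
#' @export
sortFeatures <- function(features) {
  o <- order(features$start, features$end, features$gene, method = "radix")
  out <- features[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length of each feature in bp
#' @param features a feature data.frame.
#' @return integer vector `end - start + 1`.
#' @export
featureLengths <- function(features) features$end - features$start + 1L

# Split a feature whose span crosses the circular origin (given as
# start > end on the circle) into two rows sharing the gene id.
.splitOriginSpan <- function(gene, strand, start, end, genome_length, ...) {
  data.frame(gene = gene, strand = strand,
             start = c(start, 1L), end = c(genome_length, end),
             part = c(1L, 2L), stringsAsFactors = FALSE, ...)
}
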