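# Feature-table TSV I/O.  Documented header:
#   name \t class \t strand \t start \t end \t anticodon
# 'class' and 'anticodon' are optional; class is inferred from the
# canonical vocabulary when absent.  This lets a published annotation
# table be typed in directly and analyzed with zero downloads.

#' Read gene features from a TSV table
#'
#' @param path TSV with columns `name`, `strand`, `start`, `end` and
#'   optionally `class`, `anticodon`.
#' @param genome_length optional declared genome length for span checks.
#' @return feature data.frame sorted by start (see [geneFeatures()]).
#' @examples
#' tsv <- system.file("extdata", "MN564936_features.tsv", package = "mitochar")
#' head(readFeatureTable(tsv, genome_length = 16815))
#' @export
readFeatureTable <- function(path, genome_length = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("name", "strand", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("%s: feature table needs columns: %s", path,
           paste(setdiff(need, names(df)), collapse = ", "))
  geneFeatures(
    gene = df$name, strand = df$strand, start = df$start, end = df$end,
    class = if ("class" %in% names(df)) df$class else NULL,
    anticodon = if ("anticodon" %in% names(df)) df$anticodon
                else NA_character_,
    genome_length = genome_length)
}

#' Write gene features to a TSV table
#'
#' @param features a feature data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  out <- features[, c("gene", "class", "strand", "start", "end", "anticodon")]
  names(out)[1] <- "name"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
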