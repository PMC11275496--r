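# One-call report bundle: renders the feature table, composition/skew
# table, codon/RSCU table, architecture JSON and tRNA mismatch census for
# a genome.  In feature-table-only mode (no sequence) only the
# architecture outputs are produced, with a notice.  Outputs carry no
# timestamps, so identical inputs give byte-identical files.

#' Assemble a run configuration
#'
#' @param input path to a GenBank flat file, or a feature TSV when
#'   `format = "fasta+tsv"` (with `fasta` optionally pointing at the
#'   sequence).
#' @param format `"genbank"` or `"fasta+tsv"`.
#' @param fasta optional FASTA path (fasta+tsv format).
#' @param genome_length required in feature-table-only mode.
#' @param out_dir output directory (created if needed).
#' @param precision report rounding for percentages/skews.
#' @param family_mode RSCU family partition, see [codonFamilies()].
#' @param regions gene regions for the composition table.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(input, format = c("genbank", "fasta+tsv"),
                      fasta = NULL, genome_length = NULL,
                      out_dir = ".", precision = 2,
                      family_mode = "standard",
                      regions = c("rrnS", "rrnL", "nad1", "nad2", "cox1")) {
  structure(list(input = normalizePath(input, mustWork = TRUE),
                 format = match.arg(format),
                 fasta = if (!is.null(fasta)) normalizePath(fasta, mustWork = TRUE),
                 genome_length = genome_length, out_dir = out_dir,
                 precision = precision, family_mode = family_mode,
                 regions = regions),
            class = "RunConfig")
}

#' Read/write a run configuration as YAML
#' @param path YAML file.
#' @return a `RunConfig` (for the reader); `path` invisibly (writer).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' @rdname readRunConfig
#' @param config a `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full characterization report
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return (invisibly) named character vector of the files written.
#' @export
runFullReport <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$format == "genbank") {
    gb <- readGenBank(config$input)
    genome <- gb$genome; features <- gb$features
  } else {
    genome <- if (!is.null(config$fasta)) readGenomeFasta(config$fasta)
              else circularGenome(tools::file_path_sans_ext(basename(config$input)),
                                  length = config$genome_length)
    features <- readFeatureTable(config$input,
                                 genome_length = genomeLength(genome))
  }
  out <- character(0)
  p <- function(f) file.path(config$out_dir, f)

  out["features"] <- writeFeatureTable(features, p("features.tsv"))
  arch <- analyzeArchitecture(genomeLength(genome), features,
                              circular = isCircular(genome))
  architectureJSON(arch, p("architecture.json"))
  out["architecture"] <- p("architecture.json")
  write.table(classLengths(arch), p("class_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out["class_lengths"] <- p("class_lengths.tsv")

  if (!hasSequence(genome)) {
    message("feature-table-only mode: composition, codon and tRNA reports skipped")
    return(invisible(out))
  }
  regions <- intersect(config$regions, features$gene)
  comp <- regionReport(genome, features, regions,
                       precision = config$precision)
  write.table(comp, p("composition.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  out["composition"] <- p("composition.tsv")

  pcgs <- features[features$class == "PCG", , drop = FALSE]
  if (nrow(pcgs)) {
    recs <- lapply(split(pcgs, pcgs$gene), function(f)
      extractCodons(genome, f))
    tab <- rscu(countCodons(recs, family_mode = config$family_mode))
    write.table(codonUsageReport(tab, config$precision), p("rscu.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out["rscu"] <- p("rscu.tsv")
  }

  trnas <- features[features$class == "tRNA", , drop = FALSE]
  if (nrow(trnas)) {
    folds <- lapply(split(trnas, trnas$gene), function(f) {
      f <- f[order(f$part), , drop = FALSE]
      s <- paste0(mapply(function(a, b) genomeSpan(genome, a, b, "H"),
                         f$start, f$end), collapse = "")
      if (f$strand[1] == "L") s <- revComp(s)
      foldCloverleaf(s, anticodon = f$anticodon[1], trna = f$gene[1])
    })
    write.table(mismatchCensus(folds), p("trna_census.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out["trna_census"] <- p("trna_census.tsv")
    writeLines(vapply(folds, dotBracket, ""), p("trna_folds.txt"))
    out["trna_folds"] <- p("trna_folds.txt")
  }
  invisible(out)
}
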