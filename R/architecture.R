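# Circular gene-order analytics: every consecutive gene pair on the
# circle is an overlap, an intergenic spacer or an exact adjacency.
# Pairwise classification follows the sorted mixed-strand gene order
# (strand is ignored for pairing, matching how mitogenome tables are laid
# out); total overlap/spacer bp use the occupancy definition (bp covered
# by more than one gene, bp covered by none), which stays exact even for
# nested features, so the conservation identity
#   sum(gene lengths) - overlap_bp + spacer_bp == genome_length
# holds on every circular genome.

#' Analyze overlaps, spacers and adjacencies on a circular genome
#'
#' @param genome_length declared molecule length in bp (authoritative; may
#'   exceed the last annotated coordinate, the residue then counts toward
#'   the circular closing spacer).
#' @param features feature data.frame (see [geneFeatures()]).
#' @param circular close the (last gene, first gene) pair through the
#'   origin.
#' @return an [ArchitectureReport-class].
#' @examples
#' f <- geneFeatures(c("g1", "g2"), "H", c(1, 11), c(10, 20))
#' analyzeArchitecture(20, f)
#' @export
analyzeArchitecture <- function(genome_length, features, circular = TRUE) {
  if (!nrow(features)) .stopf("need at least one feature")
  genome_length <- as.integer(genome_length)
  if (any(features$end > genome_length))
    .stopf("feature(s) beyond genome length %d", genome_length)
  gl <- .geneLevelSpans(features, genome_length)
  gl <- gl[order(gl$start, gl$end, gl$gene, method = "radix"), ]
  n <- nrow(gl)
  notes <- character(0)

  # pairwise classification on consecutive (circular) order
  ov <- sp <- ad <- list()
  npairs <- if (circular) n else n - 1L
  for (i in seq_len(max(npairs, 0L))) {
    j <- if (i == n) 1L else i + 1L
    nstart <- if (i == n) gl$start[j] + genome_length else gl$start[j]
    gap <- nstart - gl$end[i] - 1L
    pair <- data.frame(gene_a = gl$gene[i], gene_b = gl$gene[j],
                       stringsAsFactors = FALSE)
    if (gap < 0L) ov[[length(ov) + 1L]] <- cbind(pair, bp = -gap)
    else if (gap > 0L) sp[[length(sp) + 1L]] <- cbind(pair, bp = gap)
    else ad[[length(ad) + 1L]] <- pair
    if (i < n && gl$end[j] <= gl$end[i])
      notes <- c(notes, sprintf("nested feature: %s lies within %s",
                                gl$gene[j], gl$gene[i]))
  }
  emptyPairs <- data.frame(gene_a = character(0), gene_b = character(0),
                           stringsAsFactors = FALSE)
  overlaps <- if (length(ov)) do.call(rbind, ov) else cbind(emptyPairs, bp = integer(0))
  spacers  <- if (length(sp)) do.call(rbind, sp) else cbind(emptyPairs, bp = integer(0))
  adjac    <- if (length(ad)) do.call(rbind, ad) else emptyPairs

  occ <- .occupancyTotals(features, genome_length, circular)
  if (length(notes))
    .warnf("nested feature(s) detected; occupancy totals used for bp sums (%s)",
           paste(notes, collapse = "; "))
  if (!length(notes) && (occ[["overlap_bp"]] != sum(overlaps$bp) ||
                         occ[["spacer_bp"]] != sum(spacers$bp)) && circular)
    notes <- c(notes, "pairwise and occupancy totals differ (multi-way overlap)")

  totals <- c(overlap_bp = occ[["overlap_bp"]],
              overlap_count = nrow(overlaps),
              spacer_bp = occ[["spacer_bp"]],
              spacer_count = nrow(spacers),
              adjacency_count = nrow(adjac),
              spacer_frac_of_genome = occ[["spacer_bp"]] / genome_length,
              spacer_frac_of_annotated_span =
                occ[["spacer_bp"]] / max(features$end))
  new("ArchitectureReport", overlaps = overlaps, spacers = spacers,
      adjacencies = adjac, totals = totals,
      strandInventory = strandInventory(features),
      classLengths = classLengthSummary(genome_length, features),
      genomeLength = genome_length, notes = notes)
}

# collapse origin-split parts into gene-level spans; a wrapped gene gets
# an extended end coordinate (end + genome_length semantics are kept
# implicit: start of part 1, end of part 2 plus one full turn).
.geneLevelSpans <- function(features, genome_length) {
  if (all(features$part == 1L))
    return(features[, c("gene", "start", "end")])
  out <- lapply(split(features, features$gene), function(r) {
    if (nrow(r) == 1L) return(r[, c("gene", "start", "end")])
    r <- r[order(r$part), ]
    data.frame(gene = r$gene[1], start = r$start[1],
               end = r$end[nrow(r)] + genome_length, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# overlap/spacer bp by sweep over interval endpoints (distinct from the
# per-position tabulation used as the independent test oracle)
.occupancyTotals <- function(features, genome_length, circular) {
  pos <- c(features$start, features$end + 1L)
  d <- rep(c(1L, -1L), each = nrow(features))
  o <- order(pos)
  pos <- pos[o]; d <- d[o]
  cum <- cumsum(d)
  keep <- !duplicated(pos, fromLast = TRUE)   # depth after all events at a position
  upos <- pos[keep]; depthAt <- cum[keep]
  bounds <- sort(unique(c(1L, upos[upos <= genome_length], genome_length + 1L)))
  idx <- findInterval(bounds[-length(bounds)], upos)
  segdepth <- ifelse(idx == 0L, 0L, depthAt[pmax(idx, 1L)])
  seglen <- diff(bounds)
  covered <- sum(seglen[segdepth >= 1L])
  c(overlap_bp = sum(featureLengths(features)) - covered,
    spacer_bp = genome_length - covered)
}

#' Per-strand gene inventory
#'
#' @param features feature data.frame.
#' @return list with `H` and `L` data.frames (gene, class), one row per
#'   gene (origin-split parts collapsed).
#' @export
strandInventory <- function(features) {
  one <- features[!duplicated(features$gene), c("gene", "class", "strand")]
  list(H = one[one$strand == "H", c("gene", "class")],
       L = one[one$strand == "L", c("gene", "class")])
}

#' Per-class length totals and genome fractions
#'
#' Each gene contributes its full annotated length `end - start + 1`
#' (overlapping bp are not deduplicated), matching how mitogenome reports
#' total their gene classes.
#'
#' @param genome_length declared molecule length.
#' @param features feature data.frame.
#' @return data.frame per class: `total_bp`, `fraction` of genome,
#'   `n_genes`, min/max gene and their lengths.
#' @export
classLengthSummary <- function(genome_length, features) {
  glen <- tapply(featureLengths(features), features$gene, sum)
  gcls <- features$class[match(names(glen), features$gene)]
  out <- do.call(rbind, lapply(split(seq_along(glen), gcls), function(ix) {
    l <- glen[ix]
    data.frame(class = gcls[ix[1]], total_bp = sum(l),
               fraction = sum(l) / genome_length, n_genes = length(l),
               min_gene = names(l)[which.min(l)], min_bp = min(l),
               max_gene = names(l)[which.max(l)], max_bp = max(l),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @describeIn analyzeArchitecture overlap pairs (gene_a, gene_b, bp).
#' @param report an ArchitectureReport.
#' @export
overlaps <- function(report) report@overlaps

#' @describeIn analyzeArchitecture spacer pairs (gene_a, gene_b, bp).
#' @export
spacers <- function(report) report@spacers

#' @describeIn analyzeArchitecture exact adjacencies (gene_a, gene_b).
#' @export
adjacencies <- function(report) report@adjacencies

#' @describeIn analyzeArchitecture named totals vector (overlap_bp,
#'   overlap_count, spacer_bp, spacer_count, adjacency_count, spacer
#'   fractions against both genome length and annotated span).
#' @export
architectureTotals <- function(report) report@totals

#' @describeIn analyzeArchitecture per-class length summary.
#' @export
classLengths <- function(report) report@classLengths

#' Serialize an ArchitectureReport to JSON
#'
#' @param report an [ArchitectureReport-class].
#' @param path optional output file; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
architectureJSON <- function(report, path = NULL) {
  obj <- list(schema = "mitochar-architecture/1",
              genome_length = report@genomeLength,
              totals = as.list(report@totals),
              overlaps = report@overlaps, spacers = report@spacers,
              adjacencies = report@adjacencies,
              strand_inventory = lapply(report@strandInventory, identity),
              class_lengths = report@classLengths,
              notes = report@notes)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
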