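# 13-PCG supermatrix preparation: concatenate pre-aligned gene blocks
# across taxa, emit a MrBayes-ready NEXUS, and assert clade constraints on
# resulting trees.  Alignment itself and the MCMC are external steps by
# design; this module is pure pre/post-processing.

#' Build a concatenated gene supermatrix
#'
#' Genes are concatenated in `gene_set` order.  Per-gene sequences across
#' taxa must be equal length (pre-aligned input); a taxon missing a gene
#' is padded with `missing_char` over that partition.  With
#' `strip_missing = TRUE` every column containing `missing_char` or `-`
#' in any taxon is removed ("remove the missing base parts").
#'
#' @param gene_seqs named list: per gene, a named character vector of
#'   sequences (names = taxon labels).
#' @param gene_set genes to concatenate, in order (default [PCG_ORDER]).
#' @param missing_char single character used for missing data.
#' @param strip_missing drop columns containing missing data in any taxon.
#' @return a [Supermatrix-class].
#' @export
buildSupermatrix <- function(gene_seqs, gene_set = PCG_ORDER,
                             missing_char = "?", strip_missing = FALSE) {
  absent <- setdiff(gene_set, names(gene_seqs))
  if (length(absent))
    .stopf("gene(s) absent from input: %s", paste(absent, collapse = ", "))
  taxa <- sort(unique(unlist(lapply(gene_seqs[gene_set], names))))
  if (!length(taxa)) .stopf("no taxa found in gene sequences")
  rows <- setNames(rep("", length(taxa)), taxa)
  part <- data.frame(gene = character(0), start = integer(0),
                     end = integer(0), stringsAsFactors = FALSE)
  col <- 0L
  for (g in gene_set) {
    v <- gene_seqs[[g]]
    w <- unique(nchar(v))
    if (length(w) != 1L)
      .stopf("gene %s has unequal sequence lengths across taxa (%s): align first",
             g, paste(sort(w), collapse = ", "))
    pad <- strrep(missing_char, w)
    block <- ifelse(taxa %in% names(v), v[taxa], pad)
    empty <- !taxa %in% names(v)
    block[empty] <- pad
    rows <- paste0(rows, toupper(block))
    part <- rbind(part, data.frame(gene = g, start = col + 1L,
                                   end = col + w, stringsAsFactors = FALSE))
    col <- col + w
  }
  zero <- vapply(taxa, function(tx)
    all(vapply(gene_seqs[gene_set], function(v) !tx %in% names(v), TRUE)), TRUE)
  if (any(zero))
    .stopf("taxon with zero genes: %s", paste(taxa[zero], collapse = ", "))
  names(rows) <- taxa
  sm <- new("Supermatrix", taxa = taxa, sequences = rows,
            partitions = part, missingChar = missing_char)
  if (strip_missing) sm <- stripMissingColumns(sm) else sm
  sm
}

#' Remove all columns containing missing data or gaps
#'
#' @param sm a [Supermatrix-class].
#' @return a Supermatrix with offending columns deleted and partitions
#'   re-spanned (partitions reduced to zero width are dropped).
#' @export
stripMissingColumns <- function(sm) {
  m <- do.call(rbind, strsplit(sm@sequences, "", fixed = TRUE))
  bad <- apply(m == sm@missingChar | m == "-", 2, any)
  keepcols <- which(!bad)
  part <- sm@partitions
  newpart <- list()
  col <- 0L
  for (i in seq_len(nrow(part))) {
    w <- sum(keepcols >= part$start[i] & keepcols <= part$end[i])
    if (w > 0L) {
      newpart[[length(newpart) + 1L]] <-
        data.frame(gene = part$gene[i], start = col + 1L, end = col + w,
                   stringsAsFactors = FALSE)
      col <- col + w
    }
  }
  seqs <- apply(m[, keepcols, drop = FALSE], 1, paste, collapse = "")
  names(seqs) <- sm@taxa
  new("Supermatrix", taxa = sm@taxa, sequences = seqs,
      partitions = do.call(rbind, newpart), missingChar = sm@missingChar)
}

#' @describeIn buildSupermatrix taxon labels.
#' @param sm a Supermatrix.
#' @export
taxaNames <- function(sm) sm@taxa

#' @describeIn buildSupermatrix partition table (gene, start, end).
#' @export
partitions <- function(sm) sm@partitions

#' @describeIn buildSupermatrix matrix width in columns.
#' @export
matrixWidth <- function(sm) unname(nchar(sm@sequences[1]))

#' Write a Supermatrix as a MrBayes-ready NEXUS file
#'
#' Emits DATA and SETS blocks plus a `mrbayes` block with the run
#' settings; defaults encode a GTR+G+I run of four chains, 400,000
#' generations, sampling every 100, 25% burn-in.
#'
#' @param sm a [Supermatrix-class].
#' @param path output file.
#' @param settings named list overriding any of `nst`, `rates`, `ngen`,
#'   `samplefreq`, `nchains`, `burninfrac`, `outgroup`.
#' @return `path`, invisibly.
#' @export
writeMrBayesNexus <- function(sm, path, settings = list()) {
  s <- modifyList(list(nst = 6, rates = "invgamma", ngen = 400000,
                       samplefreq = 100, nchains = 4, burninfrac = 0.25,
                       outgroup = NULL), settings)
  ntax <- length(sm@taxa)
  w <- matrixWidth(sm)
  pad <- max(nchar(sm@taxa)) + 2L
  lines <- c("#NEXUS", "",
    "begin data;",
    sprintf("  dimensions ntax=%d nchar=%d;", ntax, w),
    sprintf("  format datatype=dna missing=%s gap=-;", sm@missingChar),
    "  matrix")
  for (tx in sm@taxa)
    lines <- c(lines, sprintf("    %-*s%s", pad, tx, sm@sequences[[tx]]))
  lines <- c(lines, "  ;", "end;", "", "begin sets;")
  p <- sm@partitions
  for (i in seq_len(nrow(p)))
    lines <- c(lines, sprintf("  charset %s = %d-%d;", p$gene[i],
                              p$start[i], p$end[i]))
  lines <- c(lines,
    sprintf("  partition bygene = %d: %s;", nrow(p),
            paste(p$gene, collapse = ", ")),
    "end;", "", "begin mrbayes;",
    "  set autoclose=yes nowarn=yes;",
    if (!is.null(s$outgroup)) sprintf("  outgroup %s;", s$outgroup),
    sprintf("  lset nst=%d rates=%s;", s$nst, s$rates),
    sprintf("  mcmc ngen=%d samplefreq=%d nchains=%d burninfrac=%s;",
            s$ngen, s$samplefreq, s$nchains, format(s$burninfrac)),
    "  sump; sumt;", "end;")
  writeLines(lines[!vapply(lines, is.null, TRUE)], path)
  invisible(path)
}

#' Read a NEXUS data matrix written by [writeMrBayesNexus()]
#'
#' @param path NEXUS file.
#' @return a [Supermatrix-class] (run settings are not round-tripped).
#' @export
readNexusMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^#NEXUS", lines[1])) .stopf("%s: not a NEXUS file", path)
  fmt <- grep("format datatype", lines, value = TRUE)
  missing_char <- if (length(fmt))
    sub(".*missing=(\\S).*", "\\1", fmt[1]) else "?"
  mstart <- grep("^\\s*matrix\\s*$", lines)
  if (!length(mstart)) .stopf("%s: no matrix block", path)
  i <- mstart[1] + 1L
  taxa <- character(0); seqs <- character(0)
  while (i <= length(lines) && !grepl("^\\s*;", lines[i])) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) >= 2L) { taxa <- c(taxa, f[1]); seqs <- c(seqs, f[2]) }
    i <- i + 1L
  }
  cs <- regmatches(lines, regexec(
    "charset\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+);", lines))
  cs <- cs[vapply(cs, length, 1L) == 4L]
  part <- if (length(cs)) data.frame(
    gene = vapply(cs, `[`, "", 2L),
    start = as.integer(vapply(cs, `[`, "", 3L)),
    end = as.integer(vapply(cs, `[`, "", 4L)), stringsAsFactors = FALSE)
  else data.frame(gene = "all", start = 1L, end = nchar(seqs[1]),
                  stringsAsFactors = FALSE)
  new("Supermatrix", taxa = taxa, sequences = setNames(seqs, taxa),
      partitions = part, missingChar = missing_char)
}

#' Assert nested clade constraints on a tree
#'
#' Checks that each group of a nested constraint is a clade
#' (monophyletic) in a rooted tree.  The constraint is given either as a
#' newick-style string over group labels, e.g.
#' `"((((Monticola,Saxicola),Oenanthe),Phoenicurus),Myophonus);"`, or as a
#' list of character vectors (one per group).  Constraint labels that are
#' not leaves themselves are treated as genus prefixes and expanded to all
#' matching leaves (`Genus_species` or `Genus species` labels).
#'
#' @param tree an [ape::phylo] tree (rooted; node supports optional).
#' @param constraint newick string or list of character vectors.
#' @return list with `ok` (logical) and, when violated, `witness` (the
#'   first group that is not a clade).
#' @export
assertTopology <- function(tree, constraint) {
  stopifnot(inherits(tree, "phylo"))
  groups <- if (is.character(constraint) && length(constraint) == 1L)
    .constraintGroups(constraint) else constraint
  leafsets <- .cladeLeafSets(tree)
  for (grp in groups) {
    want <- sort(unique(unlist(lapply(grp, .expandTaxon, tree = tree))))
    if (length(want) < 2L) next
    hit <- any(vapply(leafsets, function(ls) identical(sort(ls), want), TRUE))
    if (!hit) return(list(ok = FALSE, witness = want))
  }
  list(ok = TRUE, witness = NULL)
}

# expand a constraint label to matching tree leaves (exact, else prefix)
.expandTaxon <- function(label, tree) {
  tips <- tree$tip.label
  if (label %in% tips) return(label)
  hit <- tips[startsWith(tips, paste0(label, "_")) |
              startsWith(tips, paste0(label, " ")) | startsWith(tips, label)]
  if (!length(hit)) .stopf("constraint taxon '%s' matches no leaf", label)
  hit
}

# nested groups of a newick-like constraint: one group per internal node
.constraintGroups <- function(nwk) {
  if (!grepl(";\\s*$", nwk)) nwk <- paste0(nwk, ";")
  nwk <- gsub("\\s*\\+\\s*", ",", nwk)
  ct <- ape::read.tree(text = nwk)
  lapply(.cladeLeafSets(ct), identity)
}

# leaf sets of every internal node (descendant tips), accumulated along a
# postorder edge traversal
.cladeLeafSets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets[sort(unique(tree$edge[, 1]))]
}
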