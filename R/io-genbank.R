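# Minimal GenBank flat-file reader/writer for annotated mitogenomes.
# Covers the dialect these records actually use: LOCUS with length and
# circular flag, typed features (CDS, tRNA, rRNA, D-loop, misc_feature)
# with plain / complement() / join() locations, /gene /product /anticodon
# qualifiers, and an ORIGIN sequence block.  Plain `gene` keys are skipped
# (they duplicate the typed features).

.GB_KEYS <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
              "D-loop" = "control_region", misc_feature = "other")

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Feature names are normalized through the canonical vocabulary; features
#' whose names cannot be mapped are retained with the record's feature
#' class and a warning.  Features spanning the circular origin
#' (`join(x..N,1..y)`) are split into two sub-spans sharing the gene id.
#'
#' @param path GenBank flat file.
#' @return list with elements `genome` ([CircularGenome-class]) and
#'   `features` (a feature data.frame, sorted by start).
#' @seealso [writeGenBank()], [readFeatureTable()]
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    .stopf("%s: line 1: not a GenBank record (missing LOCUS)", path)
  loc <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  id <- loc[2]
  len <- suppressWarnings(as.integer(loc[3]))
  if (is.na(len))
    .stopf("%s: line 1: LOCUS line lacks a parseable length", path)
  circular <- any(grepl("circular", lines[1], ignore.case = TRUE))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  seq <- character(0)
  if (length(ostart)) {
    endl <- grep("^//", lines)
    endl <- if (length(endl)) endl[endl > ostart[1]][1] else length(lines) + 1L
    body <- lines[seq(ostart[1] + 1L, endl - 1L)]
    seq <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
    if (nchar(seq) == 0L) seq <- character(0)
  }
  genome <- circularGenome(id, seq = if (length(seq)) seq else NULL,
                           length = len, circular = circular)

  feats <- list()
  if (length(fstart)) {
    stopAt <- if (length(ostart)) ostart[1] else length(lines) + 1L
    i <- fstart[1] + 1L
    while (i < stopAt) {
      ln <- lines[i]
      m <- regmatches(ln, regexec("^ {5}(\\S+) +(\\S.*)$", ln))[[1]]
      if (length(m) == 3L && m[2] %in% names(.GB_KEYS)) {
        key <- m[2]; locstr <- m[3]
        quals <- character(0)
        j <- i + 1L
        while (j < stopAt && grepl("^ {6,}", lines[j]) &&
               !grepl("^ {5}\\S", lines[j])) {
          quals <- c(quals, trimws(lines[j])); j <- j + 1L
        }
        # continuation lines of the location itself (rare) start without '/'
        while (length(quals) && !startsWith(quals[1], "/")) {
          locstr <- paste0(locstr, quals[1]); quals <- quals[-1]
        }
        feats[[length(feats) + 1L]] <-
          .gbFeature(key, locstr, quals, len, path, i)
        i <- j
      } else i <- i + 1L
    }
  }
  features <- .assembleGbFeatures(feats, genome)
  list(genome = genome, features = features)
}

.gbQual <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
}

.gbFeature <- function(key, locstr, quals, genome_length, path, lineno) {
  comp <- grepl("^complement\\(", locstr)
  inner <- gsub("^complement\\(|\\)$", "", locstr)
  inner <- gsub("^join\\(|\\)$", "", inner)
  segs <- strsplit(inner, ",")[[1]]
  m <- regmatches(segs, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", segs))
  single <- regmatches(segs, regexec("^(\\d+)$", segs))
  starts <- ends <- integer(length(segs))
  for (k in seq_along(segs)) {
    if (length(m[[k]]) == 3L) {
      starts[k] <- as.integer(m[[k]][2]); ends[k] <- as.integer(m[[k]][3])
    } else if (length(single[[k]]) == 2L) {
      starts[k] <- ends[k] <- as.integer(single[[k]][2])
    } else
      .stopf("%s: line %d: unparseable location '%s'", path, lineno, locstr)
  }
  name <- .gbQual(quals, "gene")
  if (is.na(name)) name <- .gbQual(quals, "product")
  if (is.na(name)) name <- key
  ac <- .gbQual(quals, "anticodon")
  if (!is.na(ac)) {
    s <- regmatches(ac, regexec("seq:([A-Za-z]{3})", ac))[[1]]
    ac <- if (length(s) == 2L) toupper(s[2]) else
          if (grepl("^[A-Za-z]{3}$", ac)) toupper(ac) else NA_character_
  }
  list(key = key, name = name, starts = starts, ends = ends,
       strand = if (comp) "L" else "H", anticodon = ac)
}

.assembleGbFeatures <- function(feats, genome) {
  if (!length(feats))
    return(geneFeatures(character(0), character(0), integer(0), integer(0)))
  rows <- do.call(rbind, lapply(feats, function(f) {
    nseg <- length(f$starts)
    data.frame(name = f$name, key = f$key, strand = f$strand,
               start = f$starts, end = f$ends,
               anticodon = if (is.na(f$anticodon)) NA_character_ else f$anticodon,
               part = seq_len(nseg), stringsAsFactors = FALSE)
  }))
  gene <- normalizeGeneName(rows$name)
  unmapped <- attr(gene, "unmapped")
  class <- ifelse(unmapped, unname(.GB_KEYS[rows$key]), .classOf(gene))
  if (any(unmapped))
    .warnf("unmapped feature name(s) retained: %s",
           paste(unique(rows$name[unmapped]), collapse = ", "))
  ac <- rows$anticodon
  ac[class != "tRNA"] <- NA_character_
  df <- data.frame(gene = unname(gene), class = class, strand = rows$strand,
                   start = rows$start, end = rows$end, anticodon = ac,
                   part = rows$part, stringsAsFactors = FALSE)
  n <- genomeLength(genome)
  if (any(df$end > n))
    .stopf("feature span(s) beyond LOCUS length %d: %s", n,
           paste(df$gene[df$end > n], collapse = ", "))
  p1 <- df$part == 1L & !unmapped   # unmapped names may legitimately repeat
  dup <- unique(df$gene[p1][duplicated(df$gene[p1])])
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

#' Write a genome and its features as a GenBank flat file
#'
#' Emits the same minimal dialect [readGenBank()] consumes; reading the
#' written file recovers sequence and feature spans exactly.
#'
#' @param genome a [CircularGenome-class].
#' @param features a feature data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genome, features, path) {
  n <- genomeLength(genome)
  topo <- if (isCircular(genome)) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s     UNA",
                   genomeID(genome), n, topo),
           sprintf("DEFINITION  %s mitochondrion.", genomeID(genome)),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  keyOf <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
             control_region = "D-loop", other = "misc_feature")
  for (g in unique(features$gene)) {
    r <- features[features$gene == g, , drop = FALSE]
    r <- r[order(r$part), , drop = FALSE]
    locs <- sprintf("%d..%d", r$start, r$end)
    loc <- if (nrow(r) > 1L) sprintf("join(%s)", paste(locs, collapse = ","))
           else locs
    if (r$strand[1] == "L") loc <- sprintf("complement(%s)", loc)
    key <- keyOf[[r$class[1]]]
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", g))
    if (!is.na(r$anticodon[1]))
      out <- c(out, sprintf(
        "                     /anticodon=\"(pos:complement,aa:Xxx,seq:%s)\"",
        tolower(r$anticodon[1])))
  }
  if (hasSequence(genome)) {
    out <- c(out, "ORIGIN")
    s <- tolower(genomeSeq(genome))
    starts <- seq(1L, nchar(s), by = 60L)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59L, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
    }
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a genome sequence from a FASTA file
#'
#' @param path FASTA file with a single record.
#' @param circular topology flag to set on the genome.
#' @return a [CircularGenome-class].
#' @export
readGenomeFasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    .stopf("%s: expected exactly one FASTA record, found %d", path, length(ss))
  id <- strsplit(names(ss)[1], "[[:space:]]+")[[1]][1]
  circularGenome(id, as.character(ss[[1]]), circular = circular)
}

#' Write a genome sequence to a FASTA file
#' @inheritParams writeGenBank
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genomeSeq(genome))
  names(ss) <- genomeID(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
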