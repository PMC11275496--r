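# Canonical 37-gene vertebrate mitochondrial vocabulary and alias
# resolution.  Published annotations mix conventions freely (ND5/NAD5/nad5,
# COI/COX1/cox1, Atp8/ATP8, OH/D-loop ...), so every reader funnels names
# through this map before any analytics run.

.CANONICAL <- local({
  pcg  <- c("nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
            "cox1", "cox2", "cox3", "atp6", "atp8", "cob")
  trna <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                          "L1", "L2", "M", "N", "P", "Q", "R", "S1", "S2",
                          "T", "V", "W", "Y"))
  rrna <- c("rrnS", "rrnL")
  data.frame(
    gene  = c(pcg, trna, rrna, "d_loop"),
    class = c(rep("PCG", length(pcg)), rep("tRNA", length(trna)),
              rep("rRNA", length(rrna)), "control_region"),
    stringsAsFactors = FALSE
  )
})

# alias vectors are matched after lower-casing and stripping spaces,
# hyphens and underscores; canonical ids are implicitly their own alias.
.ALIASES <- list(
  nad1 = c("nd1", "nadh1", "nadh dehydrogenase subunit 1"),
  nad2 = c("nd2", "nadh2", "nadh dehydrogenase subunit 2"),
  nad3 = c("nd3", "nadh3", "nadh dehydrogenase subunit 3"),
  nad4 = c("nd4", "nadh4", "nadh dehydrogenase subunit 4"),
  nad4l = c("nd4l", "nadh4l", "nadh dehydrogenase subunit 4l"),
  nad5 = c("nd5", "nadh5", "nadh dehydrogenase subunit 5"),
  nad6 = c("nd6", "nadh6", "nda6", "nadh dehydrogenase subunit 6"),
  cox1 = c("coi", "co1", "coxi", "cytochrome c oxidase subunit i",
           "cytochrome c oxidase subunit 1"),
  cox2 = c("coii", "co2", "coxii", "cytochrome c oxidase subunit ii",
           "cytochrome c oxidase subunit 2"),
  cox3 = c("coiii", "co3", "coxiii", "cytochrome c oxidase subunit iii",
           "cytochrome c oxidase subunit 3"),
  atp6 = c("atpase6", "atpase 6", "atp synthase f0 subunit 6"),
  atp8 = c("atpase8", "atpase 8", "atp synthase f0 subunit 8"),
  cob  = c("cytb", "cyt b", "cob1", "cytochrome b"),
  rrnS = c("12s", "12srrna", "12s rrna", "srrna", "rrn12",
           "12s ribosomal rna", "smallsubunitribosomalrna"),
  rrnL = c("16s", "16srrna", "16s rrna", "lrrna", "rrn16",
           "16s ribosomal rna", "largesubunitribosomalrna"),
  d_loop = c("dloop", "d loop", "oh", "cr", "controlregion",
             "control region", "misc feature"),
  trnL1 = c("trnl(cun)", "trnleu(cun)", "trnl cun"),
  trnL2 = c("trnl(uur)", "trnleu(uur)", "trnl uur", "trnl(taa)"),
  trnS1 = c("trns(agy)", "trnser(agy)", "trns agy", "trns(gct)"),
  trnS2 = c("trns(ucn)", "trnser(ucn)", "trns ucn", "trns(tga)")
)

# single-letter tRNAs: trnA..trnY resolve from e.g. "tRNA-Ala"
.AA3 <- c(A = "ala", C = "cys", D = "asp", E = "glu", F = "phe", G = "gly",
          H = "his", I = "ile", K = "lys", M = "met", N = "asn", P = "pro",
          Q = "gln", R = "arg", T = "thr", V = "val", W = "trp", Y = "tyr")

.aliasTable <- local({
  tab <- character(0)
  norm <- function(s) gsub("[ _-]", "", tolower(s))
  for (g in .CANONICAL$gene) tab[norm(g)] <- g
  for (g in names(.ALIASES)) for (a in .ALIASES[[g]]) tab[norm(a)] <- g
  for (one in names(.AA3)) {
    tab[norm(paste0("trn", .AA3[[one]]))] <- paste0("trn", one)
    tab[norm(paste0("trna", .AA3[[one]]))] <- paste0("trn", one)
  }
  tab[norm("trnaleu")] <- "trnL2"   # undisambiguated Leu/Ser default to
  tab[norm("trnaser")] <- "trnS2"   # the UUR/UCN copy, flagged upstream
  tab[norm("trnleu")] <- "trnL2"
  tab[norm("trnser")] <- "trnS2"
  tab
})

#' Canonical mitochondrial gene vocabulary
#'
#' The 37-gene vertebrate mitochondrial gene set (13 protein-coding genes,
#' 22 tRNAs with the Leu1/Leu2 and Ser1/Ser2 disambiguation, 2 rRNAs) plus
#' the control region, with feature classes.
#'
#' @return a data.frame with columns `gene` and `class`
#'   (`PCG`, `tRNA`, `rRNA`, `control_region`).
#' @export
canonicalGenes <- function() .CANONICAL

#' Alias map behind gene-name normalization
#'
#' @return named character vector mapping normalized alias strings to
#'   canonical gene ids.  Alias sets are pairwise disjoint by construction
#'   (a named vector cannot hold one alias twice).
#' @seealso [normalizeGeneName()]
#' @export
geneNameMap <- function() .aliasTable

#' Normalize a raw gene name to the canonical vocabulary
#'
#' Case-insensitive total function: known aliases resolve to their
#' canonical id; unknown names are returned unchanged with attribute
#' `unmapped = TRUE` so no annotation is ever silently dropped.
#'
#' @param raw character vector of gene names as found in an annotation.
#' @return character vector of canonical ids; unmapped entries keep their
#'   input spelling and are flagged in the `unmapped` logical attribute.
#' @examples
#' normalizeGeneName(c("ND5", "COI", "tRNA-Phe", "OH"))
#' @export
normalizeGeneName <- function(raw) {
  key <- gsub("[ _-]", "", tolower(raw))
  hit <- .aliasTable[key]
  unmapped <- unname(is.na(hit))
  hit[unmapped] <- raw[unmapped]
  structure(unname(hit), unmapped = unmapped)
}

.classOf <- function(gene) {
  cls <- .CANONICAL$class[match(gene, .CANONICAL$gene)]
  ifelse(is.na(cls), "other", cls)
}

#' Canonical concatenation order of the 13 protein-coding genes
#'
#' Gene order used when protein-coding genes are concatenated into a
#' supermatrix (the conventional vertebrate mitogenome gene order of the
#' heavy-strand transcript, nad6 last).
#'
#' @format character vector of 13 canonical gene ids.
#' @export
PCG_ORDER <- c("nad1", "nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
               "nad3", "nad4l", "nad4", "nad5", "cob", "nad6")
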