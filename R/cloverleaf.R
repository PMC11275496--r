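# Template-based tRNA cloverleaf folding.
#
# The canonical cloverleaf is parameterized as consecutive segments
#   acceptor5' | spacer1 | D5' | D-loop | D3' | spacer2 |
#   AC5' | anticodon loop (7 nt) | AC3' | variable loop |
#   T5' | T-loop | T3' | acceptor3' | 3' tail
# with stem sizes acceptor 6-7, DHU 3-4, anticodon 4-5, T-psi-C 4-5,
# spacer1 1-3, spacer2 0-2, D-loop 4-12, T-loop 5-9, variable loop 3-23
# and a 0-5 nt 3' tail.  All segment-length combinations consistent with
# the sequence length are enumerated exhaustively and scored +2 per
# Watson-Crick pair, +1 per G-U wobble, -1 per other pair; the argmax is
# returned.  Ties: more stem pairs, then shorter variable loop, then the
# lexicographically smallest layout tuple (fully deterministic).

.foldCache <- new.env(parent = emptyenv())

.PAIR_SCORE <- local({
  s <- matrix(-1, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                        c("A","C","G","T","N")))
  s["A","T"] <- s["T","A"] <- s["G","C"] <- s["C","G"] <- 2
  s["G","T"] <- s["T","G"] <- 1
  s[, "N"] <- s["N", ] <- -1
  s
})

# all template layouts and their stem-pair index tables for length n
.cloverleafLayouts <- function(n) {
  key <- as.character(n)
  if (!is.null(.foldCache[[key]])) return(.foldCache[[key]])
  g <- expand.grid(a = 6:7, s1 = 1:3, d = 3:4, dl = 4:12, s2 = 0:2,
                   c = 4:5, t = 4:5, tl = 5:9, k = 0:5,
                   KEEP.OUT.ATTRS = FALSE)
  g$v <- n - (2L*g$a + g$s1 + 2L*g$d + g$dl + g$s2 + 2L*g$c + 7L +
              2L*g$t + g$tl + g$k)
  g <- g[g$v >= 3L & g$v <= 23L, , drop = FALSE]
  if (!nrow(g)) {
    out <- list(layouts = g, pairs = NULL)
    .foldCache[[key]] <- out
    return(out)
  }
  rownames(g) <- NULL
  # segment offsets per layout
  off_d5  <- g$a + g$s1
  off_d3  <- off_d5 + g$d + g$dl
  off_ac5 <- off_d3 + g$d + g$s2
  off_acl <- off_ac5 + g$c
  off_ac3 <- off_acl + 7L
  off_t5  <- off_ac3 + g$c + g$v
  off_t3  <- off_t5 + g$t + g$tl
  off_ac  <- off_t3 + g$t            # acceptor 3' side
  g$anticodon_at <- off_acl + 3L     # anticodon = loop positions 3..5
  mk <- function(len, off5, off3, arm) {
    cid <- rep.int(seq_along(len), len)
    i <- sequence(len)
    data.frame(cid = cid, arm = arm, pos5 = off5[cid] + i,
               pos3 = off3[cid] + len[cid] - i + 1L,
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(
    mk(g$a, rep.int(0L, nrow(g)), off_ac, "acceptor"),
    mk(g$d, off_d5, off_d3, "DHU"),
    mk(g$c, off_ac5, off_ac3, "anticodon"),
    mk(g$t, off_t5, off_t3, "TPC"))
  out <- list(layouts = g, pairs = pairs)
  .foldCache[[key]] <- out
  out
}

#' Fold a tRNA sequence onto the cloverleaf template
#'
#' Exhaustive search over all template segment-length combinations (see
#' the scoring and bounds described above); deterministic for identical
#' input.  When `anticodon` is supplied the anticodon-loop placement is
#' constrained so the given triplet sits at the loop center (with a
#' warning and an unconstrained fall-back if no layout can satisfy it).
#'
#' @param seq tRNA gene sequence (sense strand, DNA alphabet, 55-95 nt).
#' @param anticodon optional 3-mer (DNA or RNA alphabet).
#' @param trna optional canonical id recorded in the fold.
#' @return a [CloverleafFold-class].
#' @examples
#' \dontrun{fold <- foldCloverleaf(trnaSeq)}
#' @export
foldCloverleaf <- function(seq, anticodon = NULL, trna = "") {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 55L || n > 95L)
    .stopf("tRNA sequence length %d outside the supported 55-95 nt range", n)
  lay <- .cloverleafLayouts(n)
  g <- lay$layouts
  if (!nrow(g)) .stopf("no cloverleaf: no template layout fits %d nt", n)
  pairs <- lay$pairs
  ch <- .chars(seq)
  ch[!ch %in% rownames(.PAIR_SCORE)] <- "N"

  keep <- rep(TRUE, nrow(g))
  if (!is.null(anticodon)) {
    anticodon <- gsub("U", "T", toupper(anticodon), fixed = TRUE)
    trip <- paste0(ch[g$anticodon_at], ch[g$anticodon_at + 1L],
                   ch[g$anticodon_at + 2L])
    keep <- trip == anticodon
    if (!any(keep)) {
      .warnf("%s: no layout centers anticodon %s; folding unconstrained",
             if (nzchar(trna)) trna else "tRNA", anticodon)
      keep <- rep(TRUE, nrow(g))
    }
  }
  sc <- .PAIR_SCORE[cbind(ch[pairs$pos5], ch[pairs$pos3])]
  scoreByCid <- rowsum(sc, pairs$cid)
  goodByCid <- rowsum(as.numeric(sc > 0), pairs$cid)
  cids <- as.integer(rownames(scoreByCid))
  score <- good <- rep(-Inf, nrow(g))
  score[cids] <- scoreByCid[, 1]
  good[cids] <- goodByCid[, 1]
  score[!keep] <- -Inf
  npairs <- g$a + g$d + g$c + g$t
  # ties: more stem pairs, shorter variable loop, then lexicographically
  # smallest layout tuple -- independent of enumeration order
  ord <- order(-score, -npairs, g$v, g$a, g$s1, g$d, g$dl, g$s2, g$c,
               g$t, g$tl, g$k, method = "radix")
  best <- ord[1]
  if (good[best] < 15)
    .stopf("no cloverleaf: best layout has only %d paired (WC or G-U) positions, need >= 15",
           good[best])
  bp <- pairs[pairs$cid == best, , drop = FALSE]
  b5 <- ch[bp$pos5]; b3 <- ch[bp$pos3]
  pairKey <- paste0(b5, b3)
  cls <- ifelse(pairKey %in% c("AT", "TA", "GC", "CG"), "WC",
         ifelse(pairKey %in% c("GT", "TG"), "GU", "mismatch"))
  lyt <- g[best, c("a", "s1", "d", "dl", "s2", "c", "v", "t", "tl", "k")]
  new("CloverleafFold", trna = trna,
      pairs = data.frame(arm = bp$arm, pos5 = bp$pos5, pos3 = bp$pos3,
                         base5 = b5, base3 = b3, class = cls,
                         stringsAsFactors = FALSE),
      anticodonTriplet = paste0(ch[g$anticodon_at[best] + 0:2], collapse = ""),
      foldScore = score[best],
      layout = setNames(as.integer(lyt), names(lyt)))
}

#' @describeIn foldCloverleaf the per-pair classification table of a fold.
#' @param fold a CloverleafFold.
#' @export
foldPairs <- function(fold) fold@pairs

#' Census of wobble and mismatch pairs across folded tRNAs
#'
#' Counts non-Watson-Crick pairs per arm and overall, split into G-U
#' wobble pairs and other mismatches (mitogenome reports usually call all
#' non-WC pairs "mismatches" and note most are G-U).
#'
#' @param folds list of [CloverleafFold-class] objects.
#' @return data.frame with one row per arm plus a `total` row; columns
#'   `gu`, `other`, `non_wc`.
#' @export
mismatchCensus <- function(folds) {
  arms <- c("acceptor", "DHU", "anticodon", "TPC")
  gu <- other <- setNames(numeric(length(arms)), arms)
  for (f in folds) {
    p <- f@pairs
    for (a in arms) {
      gu[a] <- gu[a] + sum(p$arm == a & p$class == "GU")
      other[a] <- other[a] + sum(p$arm == a & p$class == "mismatch")
    }
  }
  out <- data.frame(arm = c(arms, "total"),
                    gu = c(gu, sum(gu)), other = c(other, sum(other)),
                    stringsAsFactors = FALSE)
  out$non_wc <- out$gu + out$other
  rownames(out) <- NULL
  out
}

#' Dot-bracket rendering of a cloverleaf fold
#'
#' @param fold a [CloverleafFold-class].
#' @param n sequence length (defaults to the largest paired position plus
#'   the 3' tail recorded in the layout).
#' @return a dot-bracket string: `(`/`)` for paired positions, `.` loops.
#' @export
dotBracket <- function(fold, n = NULL) {
  if (is.null(n)) n <- max(fold@pairs$pos3) + fold@layout[["k"]]
  db <- rep(".", n)
  db[fold@pairs$pos5] <- "("
  db[fold@pairs$pos3] <- ")"
  paste(db, collapse = "")
}
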