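# Independent oracles and shared fixtures.  Oracles deliberately use the
# most naive possible algorithms (per-position tabulation, full nested
# loops) so they share no code path with the package implementation.

# published M. caeruleus (MN564936) annotation, transcribed
mn564936Features <- function() {
  readFeatureTable(system.file("extdata", "MN564936_features.tsv",
                               package = "mitochar", mustWork = TRUE),
                   genome_length = 16815)
}

mn564936CodonUsage <- function() {
  read.delim(system.file("extdata", "MN564936_codon_usage.tsv",
                         package = "mitochar", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

# per-position occupancy oracle: overlap bp = sum over positions of
# (coverage - 1) where covered, spacer bp = positions covered by nothing
occupancyOracle <- function(genome_length, features) {
  cov <- integer(genome_length)
  for (i in seq_len(nrow(features))) {
    ix <- features$start[i]:features$end[i]
    cov[ix] <- cov[ix] + 1L
  }
  c(overlap_bp = sum(pmax(cov - 1L, 0L)), spacer_bp = sum(cov == 0L))
}

# random non-nested feature set on a circle (sorted, possibly
# overlapping/adjacent neighbours)
randomFeatureSet <- function(genome_length, n) {
  starts <- sort(sample.int(genome_length - 60L, n))
  lens <- sample(20:60, n, replace = TRUE)
  ends <- pmin(starts + lens - 1L, genome_length)
  keep <- !duplicated(starts)
  geneFeatures(sprintf("g%03d", seq_len(sum(keep))), "H",
               starts[keep], ends[keep], class = "other",
               genome_length = genome_length, normalize = FALSE)
}

# brute-force cloverleaf oracle: full nested-loop enumeration with
# substring scoring and the documented tie-break
bruteFoldOracle <- function(seq) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  sc1 <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("AT", "TA", "GC", "CG")) 2
    else if (p %in% c("GT", "TG")) 1 else -1
  }
  best <- NULL
  for (a in 6:7) for (s1 in 1:3) for (d in 3:4) for (dl in 4:12)
  for (s2 in 0:2) for (cc in 4:5) for (t in 4:5) for (tl in 5:9)
  for (k in 0:5) {
    v <- n - (2*a + s1 + 2*d + dl + s2 + 2*cc + 7 + 2*t + tl + k)
    if (v < 3 || v > 23) next
    off_d5 <- a + s1; off_d3 <- off_d5 + d + dl
    off_ac5 <- off_d3 + d + s2; off_ac3 <- off_ac5 + cc + 7
    off_t5 <- off_ac3 + cc + v; off_t3 <- off_t5 + t + tl
    off_acc <- off_t3 + t
    score <- 0
    for (i in 1:a)  score <- score + sc1(ch[i], ch[off_acc + a - i + 1])
    for (i in 1:d)  score <- score + sc1(ch[off_d5 + i], ch[off_d3 + d - i + 1])
    for (i in 1:cc) score <- score + sc1(ch[off_ac5 + i], ch[off_ac3 + cc - i + 1])
    for (i in 1:t)  score <- score + sc1(ch[off_t5 + i], ch[off_t3 + t - i + 1])
    cand <- list(score = score, npairs = a + d + cc + t, v = v,
                 layout = c(a = a, s1 = s1, d = d, dl = dl, s2 = s2,
                            c = cc, v = v, t = t, tl = tl, k = k))
    if (is.null(best)) { best <- cand; next }
    key  <- c(-cand$score, -cand$npairs, cand$v, a, s1, d, dl, s2, cc, t, tl, k)
    bl <- best$layout
    bkey <- c(-best$score, -best$npairs, best$v, bl[["a"]], bl[["s1"]],
              bl[["d"]], bl[["dl"]], bl[["s2"]], bl[["c"]], bl[["t"]],
              bl[["tl"]], bl[["k"]])
    for (z in seq_along(key)) {
      if (key[z] < bkey[z]) { best <- cand; break }
      if (key[z] > bkey[z]) break
    }
  }
  best
}

# small overlap-free blueprint for clean planted-structure tests
cleanMiniSpec <- function(base_freqs = c(A = .25, C = .25, G = .25, T = .25),
                          codon_weights = NULL) {
  genes <- data.frame(
    gene = c("trnF", "rrnS", "nad1", "trnI", "cox1", "trnS2", "atp8",
             "nad3", "rrnL", "d_loop"),
    class = c("tRNA", "rRNA", "PCG", "tRNA", "PCG", "tRNA", "PCG", "PCG",
              "rRNA", "control_region"),
    strand = c("H", "H", "H", "L", "H", "L", "H", "H", "H", "H"),
    length = c(68L, 300L, 312L, 70L, 452L, 75L, 166L, 351L, 400L, 200L),
    anticodon = c("GAA", NA, NA, "GAT", NA, "TGA", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  gaps <- c(1L, 3L, 0L, 5L, 2L, 1L, 0L, 10L, 2L)
  gu <- data.frame(gene = c("trnF", "trnI", "trnS2"),
                   acceptor = c(0L, 1L, 0L), DHU = c(1L, 0L, 0L),
                   anticodon = c(0L, 0L, 0L), TPC = c(0L, 0L, 1L),
                   stringsAsFactors = FALSE)
  mitoGenomeSpec(2500L, genes, gaps, base_freqs = base_freqs,
                 codon_weights = codon_weights, trna_gu = gu)
}

# same layout but with planted overlaps for architecture truth tests
overlapMiniSpec <- function() {
  sp <- cleanMiniSpec()
  gaps <- c(-1L, 3L, -2L, 5L, -4L, 1L, 0L, 10L, 2L)
  mitoGenomeSpec(2500L, sp@genes, gaps, base_freqs = sp@baseFreqs,
                 codon_weights = sp@codonWeights, trna_gu = sp@trnaGU)
}

# 17-taxon tree following the published Muscicapidae phylogeny shape
fig5Tree <- function() {
  ing <- paste0(
    "(((((Monticola_gularis,Saxicola_maurus),(Oenanthe_oenanthe,",
    "Oenanthe_isabellina)),(Phoenicurus_auroreus,Phoenicurus_phoenicurus)),",
    "Myophonus_caeruleus),((Ficedula_albicilla,(Ficedula_hyperythra,",
    "Ficedula_zanthopygia)),(Niltava_davidi,Cyornis_hainanus)))")
  nwk <- paste0("(Paradoxornis_heudei,((Muscicapa_sibirica,",
                "(Copsychus_sechellarum,Cercotrichas_coryphoeus)),",
                ing, "));")
  ape::read.tree(text = nwk)
}
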