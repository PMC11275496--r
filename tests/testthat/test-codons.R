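test_that("codon extraction types complete and incomplete stops", {
  g <- circularGenome("toy", "ATGAAATAA")
  f <- geneFeatures("nad2", "H", 1, 9, class = "PCG")
  r <- extractCodons(g, f)
  expect_equal(r$start_codon, "ATG")
  expect_equal(r$stop_codon, "TAA")
  expect_equal(r$n_codons, 3)

  g2 <- circularGenome("toy2", "GTGAAACCCTA")    # 11 bp: TA- remainder
  r2 <- extractCodons(g2, geneFeatures("cox1", "H", 1, 11, class = "PCG"))
  expect_equal(r2$start_codon, "GTG")
  expect_equal(r2$stop_codon, "TA-")

  g3 <- circularGenome("toy3", "ATGAAACCCT")     # 10 bp: T-- remainder
  r3 <- extractCodons(g3, geneFeatures("cox3", "H", 1, 10, class = "PCG"))
  expect_equal(r3$stop_codon, "T--")

  g4 <- circularGenome("toy4", "ATGAAACCCA")     # remainder A: inconsistent
  expect_warning(
    r4 <- extractCodons(g4, geneFeatures("nad4", "H", 1, 10, class = "PCG")),
    "annotation-inconsistent")
  expect_true(is.na(r4$stop_codon))

  g5 <- circularGenome("toy5", "ATGAGACCCTAA")   # internal AGA (mito stop)
  expect_warning(
    extractCodons(g5, geneFeatures("nad1", "H", 1, 12, class = "PCG")),
    "internal stop")
  expect_error(extractCodons(g5, geneFeatures("trnF", "H", 1, 12,
                                              class = "tRNA")), "PCG")
})

test_that("L-strand genes are read on the sense strand", {
  sense <- "ATGAAACCCTAA"
  g <- circularGenome("toy", revComp(sense))
  f <- geneFeatures("nad6", "L", 1, 12, class = "PCG")
  r <- extractCodons(g, f)
  expect_equal(r$start_codon, "ATG")
  expect_equal(r$codons, c("ATG", "AAA", "CCC", "TAA"))
})

test_that("planted stop types are recovered from synthetic genomes", {
  spec <- cleanMiniSpec()           # overlap-free: every feature intact
  for (seed in c(1, 2, 3)) {
    gen <- generateMitoGenome(spec, seed = seed)
    expect_true(all(gen$truth$intact))
    pcgs <- gen$features[gen$features$class == "PCG", ]
    for (i in seq_len(nrow(pcgs))) {
      r <- extractCodons(gen$genome, pcgs[i, ])
      plan <- spec@genes[spec@genes$gene == pcgs$gene[i], ]
      expect_equal(r$start_codon, plan$start_codon)
      expect_equal(r$stop_codon, plan$stop_type)
      expect_equal(length(r$flags), 0)
    }
  }
})

test_that("codon counting aggregates genes and honours include_stops", {
  g <- circularGenome("toy", "ATGTAAATGTAA")
  f1 <- geneFeatures("nad1", "H", 1, 6, class = "PCG")
  f2 <- geneFeatures("nad2", "H", 7, 12, class = "PCG")
  recs <- list(extractCodons(g, f1), extractCodons(g, f2))
  counts <- codonCounts(countCodons(recs))
  expect_equal(counts[["AUG"]], 2)
  expect_equal(counts[["UAA"]], 2)
  expect_equal(sum(counts), 4)
  nostops <- codonCounts(countCodons(recs, include_stops = FALSE))
  expect_equal(nostops[["UAA"]], 0)
  expect_equal(nostops[["AUG"]], 2)
})

test_that("codon counts on synthetic genomes equal the generator tally", {
  gen <- suppressWarnings(generateMitoGenome(overlapMiniSpec(), seed = 8))
  pcgs <- gen$features[gen$features$class == "PCG", ]
  recs <- suppressWarnings(lapply(split(pcgs, pcgs$gene),
                                  function(f) extractCodons(gen$genome, f)))
  expect_equal(codonCounts(countCodons(recs)), gen$truth$codon_counts)
  # total codons == sum floor(len/3) when stops are included
  expect_equal(sum(codonCounts(countCodons(recs))),
               sum(featureLengths(pcgs) %/% 3))
})

test_that("RSCU reproduces the published leucine and alanine examples", {
  leu <- c(UUA = 83, UUG = 38, CUU = 98, CUC = 128, CUA = 265, CUG = 66)
  ala <- c(GCU = 65, GCC = 153, GCA = 94, GCG = 21)
  r <- rscuValues(rscu(codonUsageTable(c(leu, ala))))
  expect_equal(round(r[["CUA"]], 2), 2.35)
  expect_equal(round(r[["GCG"]], 2), 0.25)
  # uniform counts within a family give RSCU 1 everywhere
  u <- rscuValues(rscu(codonUsageTable(setNames(rep(7, 4), names(ala)))))
  expect_equal(unname(u[names(ala)]), rep(1, 4))
})

test_that("the full published codon table is reproduced within 0.01", {
  cu <- mn564936CodonUsage()
  tab <- rscu(codonUsageTable(setNames(cu$count, cu$codon)))
  rep <- codonUsageReport(tab, precision = 2)
  got <- rep$rscu[match(cu$codon, rep$codon)]
  expect_true(all(abs(got - cu$rscu_published) <= 0.01 + 1e-9))
  # family ids in the default (standard-code) mode match the published
  # amino-acid column
  expect_equal(rep$family[match(cu$codon, rep$codon)], cu$aa)
})

test_that("RSCU normalization and scaling invariants hold", {
  set.seed(21)
  for (i in 1:10) {
    counts <- setNames(rpois(64, lambda = 40) + 1, mitochar:::RNA_CODONS)
    tab <- rscu(codonUsageTable(counts))
    r <- rscuValues(tab)
    fam <- codonFamilies("standard")
    for (f in unique(fam)) {
      cod <- names(fam)[fam == f]
      expect_equal(mean(r[cod]), 1, tolerance = 1e-9)
      expect_equal(sum(r[cod]), length(cod), tolerance = 1e-9)
    }
    r5 <- rscuValues(rscu(codonUsageTable(counts * 5)))
    expect_equal(r5, r, tolerance = 1e-12)
  }
  # unobserved families are reported NA, not 0
  one <- rscuValues(rscu(codonUsageTable(c(AUG = 3))))
  expect_equal(one[["AUG"]], 1)
  expect_true(is.na(one[["GGG"]]))
})

test_that("mito-code families differ from standard-code families", {
  std <- codonFamilies("standard")
  mito <- codonFamilies("mito")
  expect_equal(std[["AUA"]], "I"); expect_equal(mito[["AUA"]], "M")
  expect_equal(std[["UGA"]], "*"); expect_equal(mito[["UGA"]], "W")
  expect_equal(std[["AGA"]], "R"); expect_equal(mito[["AGA"]], "*")
  expect_equal(sum(std == "*"), 3)
  expect_equal(sum(mito == "*"), 4)
})
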