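test_that("generation is deterministic given the seed", {
  spec <- cleanMiniSpec()
  a <- generateMitoGenome(spec, seed = 7)
  b <- generateMitoGenome(spec, seed = 7)
  expect_identical(genomeSeq(a$genome), genomeSeq(b$genome))
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  c <- generateMitoGenome(spec, seed = 8)
  expect_false(identical(genomeSeq(a$genome), genomeSeq(c$genome)))
})

test_that("the default template reproduces the published architecture", {
  spec <- templateMitoSpec()
  expect_equal(nrow(spec@genes), 38)
  gen <- suppressWarnings(generateMitoGenome(spec, seed = 42))
  expect_equal(genomeLength(gen$genome), 16815)
  expect_equal(nrow(gen$features), 38)
  tr <- gen$truth$architecture
  expect_equal(tr[["overlap_count"]], 9)
  expect_equal(tr[["overlap_bp"]], 32)
  expect_equal(tr[["spacer_count"]], 22)
  expect_equal(tr[["spacer_bp"]], 403)
  expect_equal(tr[["adjacency_count"]], 7)
  # analyzer agrees with the plan
  a <- architectureTotals(analyzeArchitecture(16815, gen$features))
  expect_equal(a[names(tr)], tr)
  # planted wobble quota: 24 pairs split 8/6/3/7
  expect_equal(sum(spec@trnaGU$acceptor), 8)
  expect_equal(sum(spec@trnaGU$DHU), 6)
  expect_equal(sum(spec@trnaGU$anticodon), 3)
  expect_equal(sum(spec@trnaGU$TPC), 7)
})

test_that("uniform base frequencies give near-zero whole-genome skews", {
  # noncoding regions sample the planted composition directly (coding
  # sequence necessarily carries codon-structure skew on top)
  genes <- data.frame(gene = c("rrnS", "rrnL", "d_loop"),
                      class = c("rRNA", "rRNA", "control_region"),
                      strand = "H", length = c(6000L, 7000L, 3500L),
                      anticodon = NA, stringsAsFactors = FALSE)
  uni <- mitoGenomeSpec(16815L, genes, gaps = c(100L, 100L),
                        base_freqs = c(A = .25, C = .25, G = .25, T = .25))
  gen <- generateMitoGenome(uni, seed = 31)
  p <- composition(gen$genome)
  expect_lt(abs(p$at_skew), 0.02)
  expect_lt(abs(p$gc_skew), 0.02)
})

test_that("inconsistent blueprints are rejected before generation", {
  genes <- data.frame(gene = c("nad1", "nad2"), class = "PCG", strand = "H",
                      length = c(300L, 300L), anticodon = NA,
                      stringsAsFactors = FALSE)
  expect_error(mitoGenomeSpec(500L, genes, gaps = 0L), "inconsistent")
  expect_error(mitoGenomeSpec(800L, genes, gaps = -301L), "overlap")
  genes$stop_type <- c("TA-", "TAA")    # 300 %% 3 == 0: TA- impossible
  expect_error(mitoGenomeSpec(800L, genes, gaps = 10L), "stop plan")
})

test_that("derived taxa follow the substitution model", {
  spec <- cleanMiniSpec()
  same <- generateTaxa(spec, n_taxa = 3, per_site_sub_rate = 0, seed = 5)
  for (g in names(same$genes))
    expect_equal(length(unique(same$genes[[g]])), 1)

  rate <- 0.1
  tx <- generateTaxa(spec, n_taxa = 6, per_site_sub_rate = rate, seed = 6)
  root <- tx$root
  pcgs <- root$features[root$features$class == "PCG", ]
  nsites <- sum(featureLengths(pcgs))
  for (taxon in paste0("taxon0", 1:6)) {
    diffs <- 0
    for (g in names(tx$genes)) {
      i <- which(pcgs$gene == g)
      sense <- genomeSpan(root$genome, pcgs$start[i], pcgs$end[i],
                          strand = pcgs$strand[i])
      diffs <- diffs + sum(strsplit(sense, "")[[1]] !=
                           strsplit(tx$genes[[g]][[taxon]], "")[[1]])
    }
    sd3 <- 3 * sqrt(nsites * rate * (1 - rate))
    expect_lt(abs(diffs - nsites * rate), sd3)
  }
  expect_error(generateTaxa(spec, 2, 0.5), "0.3")
})

test_that("a 17-taxon set builds a 13-partition supermatrix", {
  taxa <- c("Myophonus_caeruleus", "Ficedula_albicilla",
            "Ficedula_hyperythra", "Ficedula_zanthopygia", "Niltava_davidi",
            "Muscicapa_sibirica", "Muscicapa_latirostris",
            "Copsychus_sechellarum", "Cercotrichas_coryphoeus",
            "Saxicola_maurus", "Monticola_gularis", "Oenanthe_oenanthe",
            "Oenanthe_isabellina", "Cyornis_hainanus",
            "Phoenicurus_auroreus", "Phoenicurus_phoenicurus",
            "Paradoxornis_heudei")
  tx <- generateTaxa(templateMitoSpec(), n_taxa = 17,
                     per_site_sub_rate = 0.05, seed = 17, taxa = taxa)
  sm <- buildSupermatrix(tx$genes)          # canonical 13-PCG order
  expect_equal(partitions(sm)$gene, PCG_ORDER)
  expect_equal(length(taxaNames(sm)), 17)
})

test_that("analyzers recover the TruthRecord across seeded genomes", {
  spec <- overlapMiniSpec()
  for (seed in 1:12) {
    gen <- suppressWarnings(generateMitoGenome(spec, seed = seed))
    truth <- gen$truth
    # architecture: exact
    a <- architectureTotals(suppressWarnings(
      analyzeArchitecture(genomeLength(gen$genome), gen$features)))
    expect_equal(a[names(truth$architecture)], truth$architecture)
    # composition: exact counts, skews to 1e-9
    p <- composition(gen$genome)
    expect_equal(c(p$a, p$c, p$g, p$t),
                 unname(truth$counts[c("A", "C", "G", "T")]))
    expect_equal(p$at_skew, truth$at_skew, tolerance = 1e-9)
    expect_equal(p$gc_skew, truth$gc_skew, tolerance = 1e-9)
    # codons: exact
    pcgs <- gen$features[gen$features$class == "PCG", ]
    recs <- suppressWarnings(lapply(split(pcgs, pcgs$gene),
                                    function(f) extractCodons(gen$genome, f)))
    expect_equal(codonCounts(countCodons(recs)), truth$codon_counts)
    # conservation identity holds on every generated genome
    expect_equal(sum(featureLengths(gen$features)) - a[["overlap_bp"]] +
                   a[["spacer_bp"]], genomeLength(gen$genome))
  }
})
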