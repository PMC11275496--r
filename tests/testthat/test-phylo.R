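test_that("supermatrix width equals the sum of gene lengths", {
  tx <- generateTaxa(cleanMiniSpec(), n_taxa = 3, per_site_sub_rate = 0.02,
                     seed = 12)
  gene_set <- names(tx$genes)
  sm <- buildSupermatrix(tx$genes, gene_set = gene_set)
  expect_equal(matrixWidth(sm),
               sum(vapply(tx$genes, function(v) nchar(v[[1]]), 1L)))
  expect_equal(partitions(sm)$gene, gene_set)
  p <- partitions(sm)
  expect_equal(p$start[1], 1)
  expect_equal(p$start[-1], p$end[-nrow(p)] + 1)
})

test_that("missing genes are padded and strip-missing removes exactly them", {
  tx <- generateTaxa(cleanMiniSpec(), n_taxa = 3, per_site_sub_rate = 0,
                     seed = 13)
  genes <- tx$genes
  w_atp8 <- nchar(genes$atp8[[1]])
  genes$atp8 <- genes$atp8[-2]               # taxon02 lacks atp8
  sm <- buildSupermatrix(genes, gene_set = names(genes))
  p <- partitions(sm)
  span <- p[p$gene == "atp8", ]
  block <- substr(sm@sequences[["taxon02"]], span$start, span$end)
  expect_equal(block, strrep("?", w_atp8))
  stripped <- stripMissingColumns(sm)
  expect_equal(matrixWidth(stripped), matrixWidth(sm) - w_atp8)
  expect_false("atp8" %in% partitions(stripped)$gene)
  # width conservation: dropped columns exactly account for the difference
  expect_equal(matrixWidth(sm),
               matrixWidth(stripped) + w_atp8)
})

test_that("degenerate supermatrix inputs are rejected", {
  genes <- list(nad1 = c(a = "ACGTAA", b = "ACGT"))
  expect_error(buildSupermatrix(genes, gene_set = "nad1"), "unequal")
  expect_error(buildSupermatrix(list(nad1 = setNames(character(0),
                                                     character(0))),
                                gene_set = "nad1"), "no taxa")
  expect_error(buildSupermatrix(list(nad1 = c(a = "ACG")),
                                gene_set = c("nad1", "nad2")), "absent")
})

test_that("MrBayes NEXUS carries the run settings and round-trips", {
  tx <- generateTaxa(cleanMiniSpec(), n_taxa = 4, per_site_sub_rate = 0.05,
                     seed = 14)
  sm <- buildSupermatrix(tx$genes, gene_set = names(tx$genes))
  nex <- tempfile(fileext = ".nex")
  writeMrBayesNexus(sm, nex, settings = list(outgroup = "taxon01"))
  lines <- readLines(nex)
  expect_true(any(grepl("ngen=400000", lines)))
  expect_true(any(grepl("samplefreq=100", lines)))
  expect_true(any(grepl("nchains=4", lines)))
  expect_true(any(grepl("burninfrac=0.25", lines)))
  expect_true(any(grepl("nst=6 rates=invgamma", lines)))
  expect_true(any(grepl("outgroup taxon01", lines)))
  rt <- readNexusMatrix(nex)
  expect_identical(rt@sequences, sm@sequences)
  expect_identical(rt@partitions, sm@partitions)
  # overridden settings are honoured
  writeMrBayesNexus(sm, nex, settings = list(ngen = 5000))
  expect_true(any(grepl("ngen=5000", readLines(nex))))
})

test_that("empty matrices are rejected", {
  expect_error(methods::new("Supermatrix", taxa = character(0),
                            sequences = character(0),
                            partitions = data.frame(), missingChar = "?"),
               "taxon")
})

test_that("nested clade constraints are asserted on the reference topology", {
  tr <- fig5Tree()
  res <- assertTopology(tr,
    "((((Monticola+Saxicola)+Oenanthe)+Phoenicurus)+Myophonus)")
  expect_true(res$ok)
  bad <- assertTopology(tr, "((Myophonus+Ficedula)+Saxicola)")
  expect_false(bad$ok)
  expect_true(length(bad$witness) > 0)
  expect_error(assertTopology(tr, list(c("Nonexistent_taxon", "Saxicola_maurus"))),
               "matches no leaf")
})

test_that("trivial pair constraint holds on a three-leaf tree", {
  tr <- ape::read.tree(text = "((A,B),C);")
  expect_true(assertTopology(tr, list(c("A", "B")))$ok)
  expect_false(assertTopology(tr, list(c("A", "C")))$ok)
})

test_that("clade assertion agrees with ape monophyly on random trees", {
  set.seed(15)
  for (rep in 1:25) {
    nt <- sample(5:10, 1)
    tr <- ape::rtree(nt)
    grp <- sample(tr$tip.label, sample(2:(nt - 1), 1))
    ours <- assertTopology(tr, list(grp))$ok
    apes <- ape::is.monophyletic(tr, grp)
    expect_equal(ours, apes)
  }
})

test_that("assertion is invariant to leaf rotation and outgroup re-rooting", {
  tr <- fig5Tree()
  con <- "((((Monticola+Saxicola)+Oenanthe)+Phoenicurus)+Myophonus)"
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_true(assertTopology(rot, con)$ok)
  rer <- ape::root(ape::unroot(tr), outgroup = "Paradoxornis_heudei",
                   resolve.root = TRUE)
  expect_true(assertTopology(rer, con)$ok)
})
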