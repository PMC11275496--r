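test_that("published annotation yields the reported architecture", {
  ft <- mn564936Features()
  a <- analyzeArchitecture(16815, ft, circular = TRUE)
  t <- architectureTotals(a)
  expect_equal(t[["overlap_count"]], 9)
  expect_equal(t[["overlap_bp"]], 32)
  expect_equal(t[["spacer_count"]], 22)
  expect_equal(t[["spacer_bp"]], 403)  # declared-length arithmetic; the
                                       # closing spacer is 297 bp
  expect_equal(t[["adjacency_count"]], 7)
  # the largest known overlap is atp8/atp6 (10 bp)
  ov <- overlaps(a)
  expect_equal(ov$bp[ov$gene_a == "atp8"], 10)
  # circular closing spacer runs from the control region back to trnF
  sp <- spacers(a)
  expect_equal(sp$bp[sp$gene_a == "d_loop" & sp$gene_b == "trnF"], 297)
})

test_that("two abutting genes on a circle give two adjacencies", {
  f <- geneFeatures(c("g1", "g2"), "H", c(1, 11), c(10, 20),
                    class = "other", normalize = FALSE)
  a <- analyzeArchitecture(20, f, circular = TRUE)
  t <- architectureTotals(a)
  expect_equal(t[["adjacency_count"]], 2)
  expect_equal(t[["overlap_count"]] + t[["spacer_count"]], 0)
})

test_that("totals equal the per-position occupancy oracle on fuzzed circles", {
  set.seed(33)
  for (rep in 1:20) {
    glen <- sample(500:2000, 1)
    f <- randomFeatureSet(glen, sample(3:50, 1))
    a <- suppressWarnings(analyzeArchitecture(glen, f, circular = TRUE))
    t <- architectureTotals(a)
    o <- occupancyOracle(glen, f)
    expect_equal(t[["overlap_bp"]], o[["overlap_bp"]])
    expect_equal(t[["spacer_bp"]], o[["spacer_bp"]])
    # conservation identity on the circle
    expect_equal(sum(featureLengths(f)) - t[["overlap_bp"]] + t[["spacer_bp"]],
                 glen)
  }
})

test_that("report is invariant under rotation of the circular origin", {
  set.seed(44)
  glen <- 1200L
  f <- randomFeatureSet(glen, 12)
  base <- architectureTotals(suppressWarnings(
    analyzeArchitecture(glen, f, circular = TRUE)))
  for (shift in c(137L, 503L)) {
    g <- f
    g$start <- ((f$start - 1L + shift) %% glen) + 1L
    g$end <- ((f$end - 1L + shift) %% glen) + 1L
    wraps <- g$end < g$start           # rotated features crossing origin
    rows <- list()
    for (i in seq_len(nrow(g))) {
      if (!wraps[i]) rows[[i]] <- g[i, ]
      else {
        r1 <- g[i, ]; r1$end <- glen; r1$part <- 1L
        r2 <- g[i, ]; r2$start <- 1L; r2$part <- 2L
        rows[[i]] <- rbind(r1, r2)
      }
    }
    g2 <- sortFeatures(do.call(rbind, rows))
    rot <- architectureTotals(suppressWarnings(
      analyzeArchitecture(glen, g2, circular = TRUE)))
    expect_equal(rot[c("overlap_bp", "spacer_bp")],
                 base[c("overlap_bp", "spacer_bp")])
  }
})

test_that("nested features warn but keep the conservation identity", {
  f <- geneFeatures(c("outer", "inner", "next1"), "H",
                    c(1, 10, 60), c(50, 20, 90),
                    class = "other", normalize = FALSE)
  expect_warning(a <- analyzeArchitecture(100, f, circular = TRUE), "nested")
  t <- architectureTotals(a)
  expect_equal(sum(featureLengths(f)) - t[["overlap_bp"]] + t[["spacer_bp"]],
               100)
})

test_that("strand inventory recovers the nine published L-strand genes", {
  ft <- mn564936Features()
  inv <- strandInventory(ft)
  expect_equal(nrow(inv$L), 9)
  expect_setequal(inv$L$gene, c("trnQ", "trnA", "trnN", "trnC", "trnY",
                                "trnS2", "trnP", "trnE", "nad6"))
  expect_equal(sum(inv$L$class == "tRNA"), 8)
  expect_equal(inv$L$gene[inv$L$class == "PCG"], "nad6")
  allH <- geneFeatures("g1", "H", 1, 10, class = "other", normalize = FALSE)
  expect_equal(nrow(strandInventory(allH)$L), 0)
})

test_that("class length summary totals published gene classes", {
  ft <- mn564936Features()
  cl <- classLengthSummary(16815, ft)
  trna <- cl[cl$class == "tRNA", ]
  expect_equal(trna$total_bp, 1546)
  expect_equal(c(trna$min_bp, trna$max_bp), c(66, 75))
  expect_equal(trna$min_gene, "trnS1")
  expect_equal(cl$total_bp[cl$class == "rRNA"], 980 + 1579)
  expect_equal(cl$total_bp[cl$class == "control_region"], 950)
  one <- geneFeatures("g1", "H", 1, 500, class = "other", normalize = FALSE)
  expect_equal(classLengthSummary(500, one)$fraction, 1)
})
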