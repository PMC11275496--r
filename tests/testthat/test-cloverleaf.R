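test_that("a fully complementary synthetic tRNA folds with zero mismatches", {
  set.seed(1)
  s <- syntheticTRNA(71, anticodon = "GAA")
  f <- foldCloverleaf(as.character(s), anticodon = "GAA", trna = "trnF")
  expect_true(all(foldPairs(f)$class == "WC"))
  expect_equal(f@anticodonTriplet, "GAA")
  census <- mismatchCensus(list(f))
  expect_equal(census$non_wc[census$arm == "total"], 0)
})

test_that("planted G-U pairs are recovered on the right arm", {
  set.seed(2)
  s <- syntheticTRNA(71, anticodon = "GAA",
                     gu = c(acceptor = 0L, DHU = 2L, anticodon = 0L, TPC = 0L))
  f <- foldCloverleaf(as.character(s), anticodon = "GAA")
  p <- foldPairs(f)
  expect_equal(sum(p$class == "GU"), 2)
  expect_true(all(p$arm[p$class == "GU"] == "DHU"))
  expect_equal(sum(p$class == "mismatch"), 0)
})

test_that("template search equals brute-force enumeration (<= 80 nt)", {
  set.seed(3)
  cases <- list(
    as.character(syntheticTRNA(68, "CAT",
      gu = c(acceptor = 1L, DHU = 0L, anticodon = 1L, TPC = 0L))),
    as.character(syntheticTRNA(74, "TGA")),
    paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE,
                 prob = c(.3, .2, .2, .3)), collapse = ""))
  for (s in cases) {
    got <- tryCatch(foldCloverleaf(s), error = function(e) e)
    want <- bruteFoldOracle(s)
    if (inherits(got, "error")) {
      # folder refuses only when even the best layout pairs poorly
      expect_match(conditionMessage(got), "no cloverleaf")
      next
    }
    expect_equal(got@foldScore, want$score)
    expect_equal(got@layout, setNames(as.integer(want$layout),
                                      names(want$layout)))
  }
})

test_that("folding is deterministic and respects length bounds", {
  set.seed(4)
  s <- as.character(syntheticTRNA(70, "GTA"))
  f1 <- foldCloverleaf(s, anticodon = "GTA")
  f2 <- foldCloverleaf(s, anticodon = "GTA")
  expect_identical(foldPairs(f1), foldPairs(f2))
  expect_identical(f1@layout, f2@layout)
  expect_error(foldCloverleaf(strrep("A", 40)), "55-95")
  expect_error(foldCloverleaf(strrep("A", 120)), "55-95")
  # a homopolymer cannot pair at all
  expect_error(foldCloverleaf(strrep("A", 70)), "no cloverleaf")
})

test_that("planted cloverleaf structure is recovered for >= 95% of tRNAs", {
  set.seed(5)
  n <- 100
  hits <- 0
  arms <- c("acceptor", "DHU", "anticodon", "TPC")
  for (i in seq_len(n)) {
    len <- sample(66:75, 1)
    gu <- setNames(rep(0L, 4), arms)
    gu[sample(arms, 1)] <- sample(0:2, 1)
    s <- syntheticTRNA(len, anticodon = "GAA", gu = gu)
    f <- foldCloverleaf(as.character(s), anticodon = "GAA")
    census <- mismatchCensus(list(f))
    got <- setNames(census$gu[match(arms, census$arm)], arms)
    if (all(got == gu) && census$other[census$arm == "total"] == 0)
      hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})

test_that("mismatch census is additive and zero on empty input", {
  empty <- mismatchCensus(list())
  expect_true(all(empty$non_wc == 0))
  set.seed(6)
  folds <- lapply(1:4, function(i) {
    gu <- setNames(as.integer(c(1, 0, 1, 0)),
                   c("acceptor", "DHU", "anticodon", "TPC"))
    foldCloverleaf(as.character(syntheticTRNA(70, "GAA", gu = gu)))
  })
  census <- mismatchCensus(folds)
  tot <- census[census$arm == "total", ]
  expect_equal(tot$gu, sum(census$gu[census$arm != "total"]))
  expect_equal(tot$non_wc, tot$gu + tot$other)
  db <- dotBracket(folds[[1]], n = 70)
  expect_equal(nchar(db), 70)
  expect_equal(sum(strsplit(db, "")[[1]] == "("),
               nrow(foldPairs(folds[[1]])))
})
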