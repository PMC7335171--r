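test_that("ECDF table follows the step-function definition", {
  e <- ecdfTable(c(1, 2, 3))
  expect_equal(e$x, c(1, 2, 3))
  expect_equal(e$F, c(1, 2, 3) / 3)
  # without ties F rises by exactly 1/N per distinct value and ends at 1
  withr::with_seed(11, {
    v <- rnorm(40)
    e2 <- ecdfTable(v)
    expect_equal(diff(e2$F), rep(1 / 40, 39))
    expect_equal(e2$F[nrow(e2)], 1)
  })
  expect_error(ecdfTable(numeric()), "at least one")
})

test_that("Mann-Whitney exact p matches the stated example and wilcox.test", {
  mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6), "two.sided")
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 0.1)
  expect_equal(mw$method, "exact")
  # identical samples: U at its midpoint, p = 1
  mw2 <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$p.value, 1)
  # agreement with the reference implementation across alternatives
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
      for (alt in c("two.sided", "greater", "less")) {
        got <- mannWhitney(a, b, alt)
        ref <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt))
        expect_equal(got$U, unname(ref$statistic))
        expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("Mann-Whitney exact p equals full enumeration for small samples", {
  withr::with_seed(17, {
    for (nA in 2:7) for (nB in 2:7) {
      a <- rnorm(nA); b <- rnorm(nB)
      for (alt in c("two.sided", "greater")) {
        expect_equal(mannWhitney(a, b, alt)$p.value,
                     enumerateMannWhitneyP(a, b, alt),
                     tolerance = 1e-12,
                     info = sprintf("nA=%d nB=%d %s", nA, nB, alt))
      }
    }
  })
})

test_that("tied data use midranks and the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5, 6, 8); b <- c(2, 3, 3, 4, 5, 7, 7, 9)
  got <- mannWhitney(a, b, "two.sided")
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(got$method, "normal")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  expect_warning(mannWhitney(rep(1, 5), rep(1, 4)), "identical")
})

test_that("intron retention summary detects a uniform +1 shift", {
  fcUp <- rep(1, 20); fcRef <- rep(0, 20)
  s <- intronRetentionSummary(
    FoldChangeTable(sprintf("g%d", 1:20), fcUp, feature = "intron"),
    fcRef, alternative = "greater")
  expect_equal(s$medianFoldChange, 2)
  expect_lt(s$result@pValue, 0.05)
  # identical distributions: median shift 0, p not small
  s0 <- intronRetentionSummary(
    FoldChangeTable(sprintf("g%d", 1:20), seq(-1, 1, length.out = 20),
                    feature = "intron"),
    seq(-1, 1, length.out = 20), alternative = "greater")
  expect_equal(s0$result@medianShift, 0)
  expect_gt(s0$result@pValue, 0.4)
  # histogram bins cover the requested range and count everything (clipped)
  expect_equal(sum(s$histogram$count_intron), 20)
  expect_equal(nrow(s$histogram), 50)
})

test_that("gene-set shift test matches enumeration and is rank-invariant", {
  withr::with_seed(23, {
    fcVals <- sort(rnorm(10))
    fc <- FoldChangeTable(sprintf("g%d", 1:10), fcVals)
    # set = the two largest fold changes among 10: exact enumeration p
    set <- GeneSet("top2", c("g9", "g10"))
    res <- genesetShiftTest(fc, set)
    expect_equal(res@pValue,
                 enumerateMannWhitneyP(fcVals[9:10], fcVals[1:8], "two.sided"),
                 tolerance = 1e-12)
    expect_equal(res@nSet, 2L)
    expect_equal(res@nBackground, 8L)
    # invariance under a strictly monotone transform of the fold changes
    fcT <- FoldChangeTable(sprintf("g%d", 1:10), exp(fcVals))
    resT <- genesetShiftTest(fcT, set)
    expect_equal(resT@U, res@U)
    expect_equal(resT@pValue, res@pValue)
    # background = "all" includes set members
    resAll <- genesetShiftTest(fc, set, background = "all")
    expect_equal(resAll@nBackground, 10L)
    # fewer than 2 members found errors and lists missing ids
    expect_error(genesetShiftTest(fc, GeneSet("bad", c("g9", "zz", "yy"))),
                 "zz")
  })
})

test_that("gene-set test keeps its type-I error near nominal", {
  withr::with_seed(31, {
    p <- replicate(400, {
      fc <- FoldChangeTable(sprintf("g%d", 1:600), rnorm(600))
      genesetShiftTest(fc, GeneSet("null", sprintf("g%d", sample(600, 40))))@pValue
    })
    expect_gt(mean(p < 0.05), 0.02)
    expect_lt(mean(p < 0.05), 0.09)
  })
})

test_that("per-gene group comparison normalises to the control mean", {
  fce <- FeatureCountExperiment(
    rbind(c(1, 1, 1, 2, 2, 2) * 100,
          c(1, 1.1, 0.9, 2.2, 1.9, 1.9) * 50),
    geneId = c("g1", "g2"), featureType = c("exon", "exon"),
    lengthBp = c(1000, 1000),
    group = rep(c("control", "case"), each = 3),
    librarySize = rep(1e6, 6))
  res <- perGeneGroupCompare(fce, c("g1", "g2"), case = "case",
                             control = "control")
  expect_equal(res$mean_control, c(1, 1))
  expect_equal(res$mean_case[1], 2)
  # constant doubled values: pooled t is exact; compare with closed form
  expect_equal(res$p_value[2],
               stats::t.test(c(2.2, 1.9, 1.9), c(1, 1.1, 0.9),
                             var.equal = TRUE)$p.value)
  # case == control values -> t = 0, p = 1
  fceEq <- FeatureCountExperiment(
    matrix(c(1, 2, 3, 1, 2, 3) * 100, nrow = 1),
    geneId = "g1", featureType = "exon", lengthBp = 1000,
    group = rep(c("control", "case"), each = 3), librarySize = rep(1e6, 6))
  resEq <- perGeneGroupCompare(fceEq, "g1", "case", "control")
  expect_equal(resEq$t, 0)
  expect_equal(resEq$p_value, 1)
  # normalized control mean is always 1
  norm <- attr(res, "normalized")
  expect_equal(unname(rowMeans(norm[, 1:3])), c(1, 1))
})
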