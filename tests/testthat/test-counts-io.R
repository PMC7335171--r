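test_that("count table round-trips through TSV unchanged", {
  fce <- tinyExperiment()
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv")
  writeCountTable(fce, p1)
  sheet <- data.frame(sample_id = c("s1", "s2"), group = c("case", "control"),
                      library_size = c(1e6, 2e6))
  back <- readCountTable(p1, sheet)
  expect_equal(sort(paste(geneId(back), featureType(back))),
               sort(paste(geneId(fce), featureType(fce))))
  ord <- order(geneId(fce), featureType(fce))
  expect_equal(unname(SummarizedExperiment::assay(back, "counts")),
               unname(SummarizedExperiment::assay(fce, "counts")[ord, ]))
  expect_equal(unname(librarySizes(back)), c(1e6, 2e6))
  # second round trip is byte-identical
  p2 <- file.path(dir, "b.tsv")
  writeCountTable(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed count tables raise errors naming the line", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("gene_id\tfeature_type\tlength_bp\ts1",
               "g1\texon\t100\t5",
               "g2\texon\t100\t-3"), bad)
  expect_error(readCountTable(bad), "line 3.*non-negative")
  writeLines(c("gene_id\tfeature_type\tlength_bp\ts1",
               "g1\tutr\t100\t5"), bad)
  expect_error(readCountTable(bad), "line 2.*exon.*intron")
  writeLines(c("gene_id\tfeature_type\tlength_bp\ts1",
               "g1\texon\t0\t5"), bad)
  expect_error(readCountTable(bad), "line 2.*positive")
  writeLines(c("gene_id\tfeature_type\tlength_bp\ts1",
               "g1\texon\t100\t5",
               "g1\texon\t100\t6"), bad)
  expect_error(readCountTable(bad), "line 3.*duplicate")
})

test_that("container invariants are enforced", {
  expect_error(FeatureCountExperiment(
    matrix(-1, 1, 1), "g", "exon", 100, "grp"), "non-negative")
  expect_error(FeatureCountExperiment(
    matrix(1, 2, 1), c("g", "g"), c("exon", "exon"), c(100, 100), "grp"),
    "duplicate")
})

test_that("overlap counting assigns reads with exon priority", {
  feat <- simpleFeatures()
  # read fully inside the exon
  r1 <- countFeatureReads(bedRead(50, 60), feat)
  cts <- SummarizedExperiment::assay(r1, "counts")[, 1]
  expect_equal(unname(cts[featureType(r1) == "exon"]), 1)
  expect_equal(unname(cts[featureType(r1) == "intron"]), 0)
  # junction-spanning read counts as exonic only
  r2 <- countFeatureReads(bedRead(95, 105), feat)
  cts <- SummarizedExperiment::assay(r2, "counts")[, 1]
  expect_equal(unname(cts[featureType(r2) == "exon"]), 1)
  expect_equal(unname(cts[featureType(r2) == "intron"]), 0)
  # purely intronic read
  r3 <- countFeatureReads(bedRead(150, 160), feat)
  cts <- SummarizedExperiment::assay(r3, "counts")[, 1]
  expect_equal(unname(cts[featureType(r3) == "intron"]), 1)
  # feature lengths are merged spans
  expect_equal(featureLength(r1)[featureType(r1) == "exon"], 100)
  expect_equal(featureLength(r1)[featureType(r1) == "intron"], 100)
  # empty features give an empty table
  empty <- countFeatureReads(bedRead(1, 10), simpleFeatures()[0])
  expect_equal(nrow(empty), 0)
})

test_that("overlap counting matches the all-pairs oracle on random input", {
  withr::with_seed(42, {
    feat <- data.frame(
      gene_id = rep(sprintf("g%02d", 1:10), each = 4),
      feature_type = rep(c("exon", "intron", "exon", "intron"), 10),
      start = rep(seq(0, 9000, by = 1000), each = 4) + c(0, 250, 500, 750),
      end = rep(seq(0, 9000, by = 1000), each = 4) + c(250, 500, 750, 1000))
    gr <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(start = feat$start + 1, end = feat$end),
      gene_id = feat$gene_id, feature_type = feat$feature_type)
    rs <- sample(0:10200, 1000, replace = TRUE)
    re <- rs + sample(20:150, 1000, replace = TRUE)
    got <- countFeatureReads(bedRead(rs, re), gr)
    want <- bruteForceCounts(rs, re, feat)
    key <- paste(geneId(got), featureType(got))
    expect_equal(unname(SummarizedExperiment::assay(got, "counts")[, 1]),
                 unname(want[key]))
  })
})

test_that("expression filter applies the strict <1 mean rule and is idempotent", {
  mk <- function(countsA, countsB) FeatureCountExperiment(
    rbind(countsA, countsB), geneId = c("g1", "g1"),
    featureType = c("exon", "intron"), lengthBp = c(100, 100),
    group = rep("g", length(countsA)))
  # summed mean (0+0+1 + 0)/3 = 0.33 -> excluded
  expect_equal(nrow(filterLowExpression(mk(c(0, 0, 1), c(0, 0, 0)))), 0)
  # boundary: mean exactly 1 -> retained, both feature rows kept
  expect_equal(nrow(filterLowExpression(mk(c(0, 1, 2), c(0, 0, 0)))), 2)
  # threshold 0 keeps everything; idempotence
  fce <- tinyExperiment()
  expect_equal(nrow(filterLowExpression(fce, 0)), nrow(fce))
  once <- filterLowExpression(fce)
  twice <- filterLowExpression(once)
  expect_equal(SummarizedExperiment::assay(once), SummarizedExperiment::assay(twice))
  expect_error(filterLowExpression(fce, -1), "non-negative")
})

test_that("densities follow the RPM definitions", {
  fce <- computeDensity(tinyExperiment())
  rpm <- SummarizedExperiment::assay(fce, "rpm")
  dens <- SummarizedExperiment::assay(fce, "density_per_kb")
  # count 10, library 1e6 -> rpm 10; count 20, library 2e6 -> rpm 10
  expect_equal(unname(rpm[1, ]), c(10, 10))
  # count 100, length 500, library 1e6 -> density 100/0.5 = 200
  expect_equal(unname(dens[3, "s1"]), 200)
  expect_equal(unname(rpm[4, ]), c(0, 0))
  # per-sample RPM sums to 1e6 * assigned/library
  cts <- SummarizedExperiment::assay(fce, "counts")
  expect_equal(unname(colSums(rpm)),
               unname(1e6 * colSums(cts) / librarySizes(fce)))
  # missing library size falls back to assigned totals with a warning
  noLib <- tinyExperiment()
  SummarizedExperiment::colData(noLib)$library_size <- NA_real_
  expect_warning(withLib <- computeDensity(noLib), "library_size missing")
  expect_equal(unname(librarySizes(withLib)),
               unname(colSums(SummarizedExperiment::assay(noLib, "counts"))))
})

test_that("fold changes use the pseudo-count and are antisymmetric", {
  # case 0, control 0 -> log2((0+.1)/(0+.1)) = 0
  fce <- computeDensity(tinyExperiment())
  fc <- foldChange(fce, "case", "control", feature = "gene")
  expect_s4_class(fc, "FoldChangeTable")
  expect_equal(fc["gA", "log2fc"], 0)  # rpm 10 vs 10
  # case mean 0.9, control mean 0.1, pseudo 0.1 -> log2(5)
  fce2 <- FeatureCountExperiment(
    matrix(c(9, 1), 1, 2, dimnames = list(NULL, c("a", "b"))),
    "g1", "exon", 1000, c("case", "control"), librarySize = c(1e7, 1e7))
  fc2 <- foldChange(fce2, "case", "control", feature = "gene")
  expect_equal(fc2$log2fc, log2(5), tolerance = 1e-12)
  # group swap negates every fold change
  fwd <- foldChange(fce, "case", "control", feature = "intron")
  rev <- foldChange(fce, "control", "case", feature = "intron")
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_error(foldChange(fce, "case", "nope"), "unknown group")
  expect_error(foldChange(fce, "case", "control", pseudo = 0), "positive")
})
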