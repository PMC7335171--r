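# fixtures built in code, shared across test files

# tiny two-gene, two-sample count experiment with known numbers
tinyExperiment <- function() {
  FeatureCountExperiment(
    counts = matrix(c(10, 2, 100, 0,
                      20, 4, 200, 0), ncol = 2,
                    dimnames = list(NULL, c("s1", "s2"))),
    geneId = c("gA", "gA", "gB", "gB"),
    featureType = c("exon", "intron", "exon", "intron"),
    lengthBp = c(1000, 2000, 500, 1500),
    group = c("case", "control"),
    librarySize = c(1e6, 2e6))
}

# write a count table TSV and return its path
tinyCountTsv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  writeCountTable(tinyExperiment(), path)
  path
}

# GRanges feature set: one gene, exon [0,100) + intron [100,200) in BED terms
simpleFeatures <- function() {
  GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1, 101), end = c(100, 200)),
    gene_id = "g1", feature_type = c("exon", "intron"))
}

bedRead <- function(starts, ends) {
  GenomicRanges::GRanges("chr1",
                         IRanges::IRanges(start = starts + 1, end = ends))
}

# all-pairs overlap oracle implementing the exon-priority assignment rule on
# 0-based half-open coordinates
bruteForceCounts <- function(readStart, readEnd, feat) {
  keys <- unique(feat[c("gene_id", "feature_type")])
  counts <- stats::setNames(rep(0, nrow(keys)),
                            paste(keys$gene_id, keys$feature_type))
  for (i in seq_along(readStart)) {
    for (g in unique(feat$gene_id)) {
      fg <- feat[feat$gene_id == g, ]
      ov <- function(type) {
        f <- fg[fg$feature_type == type, ]
        any(readStart[i] < f$end & f$start < readEnd[i])
      }
      if (ov("exon")) {
        counts[paste(g, "exon")] <- counts[paste(g, "exon")] + 1
      } else if (ov("intron")) {
        counts[paste(g, "intron")] <- counts[paste(g, "intron")] + 1
      }
    }
  }
  counts
}

# exact Mann-Whitney p by enumerating all labelings of the combined sample
enumerateMannWhitneyP <- function(x, y, alternative) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, uOf)
  switch(alternative,
         greater = mean(us >= uObs),
         less = mean(us <= uObs),
         two.sided = min(1, 2 * min(mean(us >= uObs), mean(us <= uObs))))
}
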