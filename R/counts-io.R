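#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id`, `group` and optionally
#'   `library_size` (uniquely mapped reads).
#' @return data frame with unique `sample_id`s and non-empty `group`s.
#' @export
readSampleSheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stopIfNot(all(c("sample_id", "group") %in% colnames(sheet)),
             "sample sheet needs columns sample_id and group")
  .stopIfNot(!anyDuplicated(sheet$sample_id), "duplicate sample_id in sample sheet")
  .stopIfNot(all(nzchar(sheet$group) & !is.na(sheet$group)),
             "every sample must have a group")
  if (!"library_size" %in% colnames(sheet)) sheet$library_size <- NA_real_
  sheet
}

#' Write a sample sheet
#' @param sheet data frame as returned by [readSampleSheet()].
#' @param path output CSV path.
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.csv(sheet[order(sheet$sample_id), , drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-gene exon/intron count table
#'
#' The TSV header is `gene_id`, `feature_type`, `length_bp` followed by one
#' column per sample.  Every violation of the container invariants (unknown
#' feature type, non-positive length, negative or non-numeric count, duplicate
#' key) raises an error naming the offending file line.
#'
#' @param path TSV path.
#' @param sampleSheet optional data frame (see [readSampleSheet()]) supplying
#'   group labels and library sizes; sample columns are matched by name.
#' @return A [FeatureCountExperiment-class].
#' @export
readCountTable <- function(path, sampleSheet = NULL) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  fixed <- c("gene_id", "feature_type", "length_bp")
  .stopIfNot(all(fixed %in% colnames(raw)) && ncol(raw) > 3L,
             "count table header must be gene_id, feature_type, length_bp, <samples...>")
  sampleCols <- setdiff(colnames(raw), fixed)
  lineOf <- function(i) i + 1L  # header occupies line 1

  bad <- which(!raw$feature_type %in% c("exon", "intron"))
  if (length(bad))
    stop("line ", lineOf(bad[1]), ": feature_type must be 'exon' or 'intron'")
  len <- suppressWarnings(as.numeric(raw$length_bp))
  bad <- which(is.na(len) | len <= 0)
  if (length(bad))
    stop("line ", lineOf(bad[1]), ": length_bp must be a positive number")
  counts <- matrix(suppressWarnings(as.numeric(as.matrix(raw[sampleCols]))),
                   nrow = nrow(raw), dimnames = list(NULL, sampleCols))
  bad <- which(apply(is.na(counts) | counts < 0, 1L, any))
  if (length(bad))
    stop("line ", lineOf(bad[1]), ": counts must be non-negative numbers")
  key <- paste(raw$gene_id, raw$feature_type)
  bad <- which(duplicated(key))
  if (length(bad))
    stop("line ", lineOf(bad[1]), ": duplicate (gene_id, feature_type) key")

  group <- "ungrouped"
  libSize <- NA_real_
  if (!is.null(sampleSheet)) {
    missing <- setdiff(sampleCols, sampleSheet$sample_id)
    .stopIfNot(length(missing) == 0,
               "samples absent from sample sheet: ", paste(missing, collapse = ", "))
    idx <- match(sampleCols, sampleSheet$sample_id)
    group <- sampleSheet$group[idx]
    if ("library_size" %in% colnames(sampleSheet))
      libSize <- sampleSheet$library_size[idx]
  }
  FeatureCountExperiment(counts, geneId = raw$gene_id,
                         featureType = raw$feature_type, lengthBp = len,
                         group = group, librarySize = libSize)
}

#' Write a count table as TSV
#'
#' Rows are sorted by `gene_id` then `feature_type` and samples are written in
#' object order, so output is deterministic for a given object.
#'
#' @param object a [FeatureCountExperiment-class].
#' @param path output TSV path.
#' @export
writeCountTable <- function(object, path) {
  df <- data.frame(gene_id = geneId(object),
                   feature_type = featureType(object),
                   length_bp = featureLength(object),
                   as.data.frame(assay(object, "counts")),
                   check.names = FALSE)
  df <- df[order(df$gene_id, df$feature_type), , drop = FALSE]
  .writeTsv(df, path)
}

#' Read exon and intron interval BED files as a feature set
#'
#' BED is 0-based half-open on disk; import converts to the 1-based closed
#' GRanges convention, so overlap semantics are preserved.  The BED `name`
#' field is interpreted as the gene identifier.
#'
#' @param exonPath,intronPath BED file paths (BED6 or BED4; score/strand
#'   unused — overlap counting ignores strand).
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `feature_type`.
#' @export
readFeatureBed <- function(exonPath, intronPath) {
  tag <- function(path, type) {
    gr <- rtracklayer::import(path, format = "BED")
    .stopIfNot(!is.null(gr$name) && all(nzchar(gr$name)),
               "BED name field must carry the gene_id: ", path)
    gr$gene_id <- gr$name
    gr$feature_type <- type
    gr$name <- NULL
    gr
  }
  c(tag(exonPath, "exon"), tag(intronPath, "intron"))
}

#' Count reads per gene feature with exon priority
#'
#' Each read is assigned, independently for every gene it touches, to at most
#' one feature class: a read overlapping (by at least 1 bp) any exon of the
#' gene is exonic for that gene; otherwise, if it overlaps an intron of the
#' gene, it is intronic.  This exon-priority rule keeps junction-spanning reads
#' from being double counted.  Feature lengths are the merged (reduced) span of
#' each gene's exon or intron intervals.  Strand is ignored.
#'
#' @param reads a [GenomicRanges::GRanges] of read positions, or a BED path.
#' @param features a `GRanges` with metadata columns `gene_id` and
#'   `feature_type` (see [readFeatureBed()]).
#' @param sampleId column name for the single resulting sample.
#' @param group group label for the sample.
#' @return A single-sample [FeatureCountExperiment-class]; empty features give
#'   an empty table.
#' @export
countFeatureReads <- function(reads, features, sampleId = "sample_1",
                              group = "ungrouped") {
  if (is.character(reads))
    reads <- rtracklayer::import(reads, format = "BED")
  .stopIfNot(methods::is(reads, "GRanges") && methods::is(features, "GRanges"),
             "reads and features must be GRanges (or BED paths for reads)")
  .stopIfNot(all(c("gene_id", "feature_type") %in%
                   colnames(S4Vectors::mcols(features))),
             "features need metadata columns gene_id and feature_type")

  featKey <- paste(features$gene_id, features$feature_type)
  spans <- vapply(split(features, featKey),
                  function(gr) sum(GenomicRanges::width(GenomicRanges::reduce(gr))),
                  numeric(1))
  featTab <- unique(data.frame(gene_id = features$gene_id,
                               feature_type = features$feature_type,
                               stringsAsFactors = FALSE))
  featTab <- featTab[order(featTab$gene_id, featTab$feature_type), , drop = FALSE]
  if (nrow(featTab) == 0L)
    return(FeatureCountExperiment(matrix(numeric(), 0, 1,
                                         dimnames = list(NULL, sampleId)),
                                  character(), character(), numeric(),
                                  group = group))
  featTab$length_bp <- spans[paste(featTab$gene_id, featTab$feature_type)]

  hits <- GenomicRanges::findOverlaps(reads, features, minoverlap = 1L,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  gene <- features$gene_id[S4Vectors::subjectHits(hits)]
  type <- features$feature_type[S4Vectors::subjectHits(hits)]
  # one assignment per (read, gene): exon wins over intron
  pair <- paste(q, gene)
  exonic <- unique(pair[type == "exon"])
  intronic <- setdiff(unique(pair[type == "intron"]), exonic)
  tally <- function(pairs) {
    g <- sub("^\\S+ ", "", pairs)
    table(factor(g, levels = unique(featTab$gene_id)))
  }
  exCount <- tally(exonic)
  inCount <- tally(intronic)
  cnt <- ifelse(featTab$feature_type == "exon",
                as.numeric(exCount[featTab$gene_id]),
                as.numeric(inCount[featTab$gene_id]))
  m <- matrix(cnt, ncol = 1, dimnames = list(NULL, sampleId))
  FeatureCountExperiment(m, geneId = featTab$gene_id,
                         featureType = featTab$feature_type,
                         lengthBp = featTab$length_bp, group = group)
}

#' Exclude weakly expressed genes
#'
#' Retains genes whose mean read count per sample, summed over the gene's
#' feature rows, is at least `threshold`; both feature rows of a gene are kept
#' or dropped together.  With the default threshold of 1 this is the strict
#' "fewer than 1 read per sample on average" exclusion; genes at exactly the
#' threshold are retained.  The operation is idempotent.
#'
#' @param object a [FeatureCountExperiment-class].
#' @param threshold non-negative minimum mean reads/sample (default 1).
#' @return The filtered [FeatureCountExperiment-class].
#' @export
filterLowExpression <- function(object, threshold = 1) {
  .stopIfNot(length(threshold) == 1L && is.finite(threshold) && threshold >= 0,
             "threshold must be a single non-negative number")
  .stopIfNot(ncol(object) >= 1L, "at least one sample is required")
  perGene <- rowsum(rowSums(assay(object, "counts")), geneId(object))
  meanPerSample <- perGene[, 1] / ncol(object)
  keep <- rownames(perGene)[meanPerSample >= threshold]
  object[geneId(object) %in% keep, ]
}

#' Compute RPM and per-kilobase read densities
#'
#' Adds `rpm` (reads per million uniquely mapped reads) and `density_per_kb`
#' (`rpm / (length_bp/1000)`) assays.  Samples lacking a library size fall
#' back to their total assigned read count, with a warning, because the
#' intended normaliser is uniquely mapped reads.
#'
#' @param object a [FeatureCountExperiment-class].
#' @return The object with `rpm` and `density_per_kb` assays; samples whose
#'   library size was estimated are flagged in
#'   `colData(object)$library_size_estimated`.
#' @export
computeDensity <- function(object) {
  cts <- assay(object, "counts")
  lib <- librarySizes(object)
  estimated <- is.na(lib)
  if (any(estimated)) {
    warning("library_size missing for ",
            paste(colnames(object)[estimated], collapse = ", "),
            "; using total assigned reads (uniquely mapped totals are preferred)")
    lib[estimated] <- colSums(cts)[estimated]
  }
  .stopIfNot(all(lib > 0), "library sizes must be positive")
  rpm <- sweep(cts, 2L, lib, function(c, l) c * 1e6 / l)
  dens <- rpm / (featureLength(object) / 1000)
  assay(object, "rpm") <- rpm
  assay(object, "density_per_kb") <- dens
  colData(object)$library_size <- unname(lib)
  colData(object)$library_size_estimated <- unname(estimated)
  methods::validObject(object)
  object
}

#' Pseudo-count-stabilised log2 fold changes between groups
#'
#' For each feature, `log2fc = log2((mean case value + pseudo) /
#' (mean control value + pseudo))`.  The contrasted value depends on
#' `feature`: `"gene"` uses the gene's exonic RPM (mRNA abundance),
#' `"intron"` and `"exon"` use the per-kilobase read density of the
#' corresponding feature rows.  The pseudo-count (default 0.1 RPM) keeps all
#' fold changes finite and damps low-count noise.
#'
#' @param object a [FeatureCountExperiment-class]; densities are computed on
#'   the fly if absent.
#' @param case,control group labels to contrast.
#' @param pseudo positive pseudo-count added to both means (default 0.1).
#' @param feature `"gene"`, `"intron"` or `"exon"`.
#' @return A [FoldChangeTable-class] with one row per gene feature.
#' @export
foldChange <- function(object, case, control, pseudo = 0.1,
                       feature = c("gene", "intron", "exon")) {
  feature <- match.arg(feature)
  .stopIfNot(length(pseudo) == 1L && is.finite(pseudo) && pseudo > 0,
             "pseudo must be a single positive number")
  grp <- sampleGroups(object)
  for (g in c(case, control))
    .stopIfNot(g %in% grp, "unknown group: ", g)
  if (!"rpm" %in% assayNames(object))
    object <- computeDensity(object)
  rowType <- if (feature == "gene") "exon" else feature
  assayName <- if (feature == "gene") "rpm" else "density_per_kb"
  sel <- featureType(object) == rowType
  vals <- assay(object, assayName)[sel, , drop = FALSE]
  caseMean <- rowMeans(vals[, grp == case, drop = FALSE])
  ctrlMean <- rowMeans(vals[, grp == control, drop = FALSE])
  df <- DataFrame(gene_id = geneId(object)[sel],
                  case_mean = unname(caseMean),
                  control_mean = unname(ctrlMean),
                  log2fc = unname(log2((caseMean + pseudo) / (ctrlMean + pseudo))))
  rownames(df) <- df$gene_id
  new("FoldChangeTable", df, caseGroup = case, controlGroup = control,
      pseudo = pseudo, feature = feature)
}
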