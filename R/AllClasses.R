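#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assay<-
#'   rowData colData colData<- assayNames
NULL

## ---------------------------------------------------------------------------
## FeatureCountExperiment
## ---------------------------------------------------------------------------

#' Per-gene exon/intron read counts across labelled samples
#'
#' `FeatureCountExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with one row per (gene, feature type) pair, where the feature type is either
#' `"exon"` (all exonic positions of the gene, merged) or `"intron"` (all
#' intronic positions).  Row metadata carries `gene_id`, `feature_type` and the
#' merged feature length in base pairs; column metadata carries the sample
#' `group` label and, optionally, the `library_size` (uniquely mapped reads)
#' used for reads-per-million (RPM) normalisation.
#'
#' @slot ... inherited from `SummarizedExperiment`; the `"counts"` assay holds
#'   non-negative read counts.
#'
#' @seealso [readCountTable()], [computeDensity()], [foldChange()]
#' @export
setClass("FeatureCountExperiment", contains = "SummarizedExperiment")

setValidity("FeatureCountExperiment", function(object) {
  msg <- character()
  rd <- rowData(object)
  required <- c("gene_id", "feature_type", "length_bp")
  if (!all(required %in% colnames(rd)))
    return(paste("rowData must contain columns:", paste(required, collapse = ", ")))
  if (!all(rd$feature_type %in% c("exon", "intron")))
    msg <- c(msg, "feature_type must be 'exon' or 'intron'")
  if (any(!is.finite(rd$length_bp)) || any(rd$length_bp <= 0))
    msg <- c(msg, "length_bp must be positive and finite")
  key <- paste(rd$gene_id, rd$feature_type)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (gene_id, feature_type) rows")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cts <- assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
      msg <- c(msg, "counts must be finite and non-negative")
  }
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (any(is.na(cd$group)) || any(!nzchar(cd$group)))
    msg <- c(msg, "every sample must have a non-empty group label")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample names must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureCountExperiment
#'
#' @param counts integer-like matrix of read counts, one row per
#'   (gene, feature type) pair, one column per sample.
#' @param geneId character vector of gene identifiers, one per row.
#' @param featureType character vector, `"exon"` or `"intron"`, one per row.
#' @param lengthBp positive numeric vector of merged feature lengths (bp).
#' @param group character vector of group labels, one per sample.
#' @param librarySize optional numeric vector of uniquely mapped read totals
#'   per sample; `NA` means "derive from column sums when densities are
#'   computed" (a warning is then emitted, because the reference normalisation
#'   uses uniquely mapped reads, not assigned reads).
#'
#' @return A validated [FeatureCountExperiment-class] object.
#' @export
FeatureCountExperiment <- function(counts, geneId, featureType, lengthBp,
                                   group, librarySize = NA_real_) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  rd <- DataFrame(gene_id = as.character(geneId),
                  feature_type = as.character(featureType),
                  length_bp = as.numeric(lengthBp))
  cd <- DataFrame(group = as.character(rep_len(group, ncol(counts))),
                  library_size = as.numeric(rep_len(librarySize, ncol(counts))),
                  row.names = colnames(counts))
  rownames(counts) <- paste(rd$gene_id, rd$feature_type, sep = ":")
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd)
  new("FeatureCountExperiment", se)
}

#' @describeIn FeatureCountExperiment gene identifier of each row.
#' @param object,x a `FeatureCountExperiment`.
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))

#' @export
setMethod("geneId", "FeatureCountExperiment",
          function(object) rowData(object)$gene_id)

#' @describeIn FeatureCountExperiment feature type (`"exon"`/`"intron"`) of
#'   each row.
#' @export
setGeneric("featureType", function(object) standardGeneric("featureType"))

#' @export
setMethod("featureType", "FeatureCountExperiment",
          function(object) rowData(object)$feature_type)

#' @describeIn FeatureCountExperiment merged feature length in bp.
#' @export
setGeneric("featureLength", function(object) standardGeneric("featureLength"))

#' @export
setMethod("featureLength", "FeatureCountExperiment",
          function(object) rowData(object)$length_bp)

#' @describeIn FeatureCountExperiment sample group labels.
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @export
setMethod("sampleGroups", "FeatureCountExperiment",
          function(object) stats::setNames(colData(object)$group, colnames(object)))

#' @describeIn FeatureCountExperiment per-sample library sizes (NA when not
#'   supplied).
#' @export
setGeneric("librarySizes", function(object) standardGeneric("librarySizes"))

#' @export
setMethod("librarySizes", "FeatureCountExperiment",
          function(object) stats::setNames(colData(object)$library_size, colnames(object)))

setMethod("show", "FeatureCountExperiment", function(object) {
  cat("FeatureCountExperiment with", length(unique(geneId(object))), "genes,",
      nrow(object), "feature rows,", ncol(object), "samples\n")
  grp <- table(colData(object)$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "), "\n")
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## GeneSet
## ---------------------------------------------------------------------------

#' A named set of gene identifiers
#'
#' Lightweight container for published gene lists (e.g. NMD-target sets or
#' canonical histone genes) used by [genesetShiftTest()].
#'
#' @slot name single descriptive name.
#' @slot members unique, non-empty character vector of gene identifiers.
#' @slot source free-text provenance.
#' @export
setClass("GeneSet",
         representation(name = "character", members = "character",
                        source = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@members) == 0L)
    msg <- c(msg, "gene set must be non-empty")
  if (anyDuplicated(object@members))
    msg <- c(msg, "gene set members must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @param name set name.
#' @param members character vector of gene identifiers (deduplicated).
#' @param source free-text provenance.
#' @export
GeneSet <- function(name, members, source = "") {
  new("GeneSet", name = as.character(name),
      members = unique(as.character(members)),
      source = as.character(source))
}

#' Read a gene set from a plain-text file (one identifier per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param name set name; defaults to the file name without extension.
#' @param source free-text provenance.
#' @return A [GeneSet-class].
#' @export
readGeneSet <- function(path, name = NULL, source = path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  GeneSet(name, lines, source = source)
}

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d members", object@name, length(object@members)))
  if (nzchar(object@source)) cat(" [", object@source, "]", sep = "")
  cat("\n")
})

## ---------------------------------------------------------------------------
## FoldChangeTable
## ---------------------------------------------------------------------------

#' Per-feature log2 fold changes between two sample groups
#'
#' A `DataFrame` subclass (one row per gene feature, columns `gene_id`,
#' `case_mean`, `control_mean`, `log2fc`) carrying the contrast definition in
#' dedicated slots.  Fold changes are computed from pseudo-count-stabilised
#' group means, so `log2fc` is always finite.
#'
#' @slot caseGroup,controlGroup the contrasted group labels.
#' @slot pseudo the pseudo-RPM constant added to both group means (default 0.1).
#' @slot feature which quantity was contrasted: `"gene"` (gene RPM, exon
#'   reads), `"intron"` or `"exon"` (per-kb read density).
#' @export
setClass("FoldChangeTable", contains = "DFrame",
         representation(caseGroup = "character", controlGroup = "character",
                        pseudo = "numeric", feature = "character"))

setValidity("FoldChangeTable", function(object) {
  msg <- character()
  need <- c("gene_id", "case_mean", "control_mean", "log2fc")
  if (!all(need %in% colnames(object)))
    return(paste("columns required:", paste(need, collapse = ", ")))
  if (any(!is.finite(object$log2fc)))
    msg <- c(msg, "log2fc must be finite (pseudo > 0 guarantees this)")
  if (length(object@pseudo) != 1L || object@pseudo <= 0)
    msg <- c(msg, "pseudo must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname FoldChangeTable-class
#' @param geneId character vector of gene identifiers.
#' @param log2fc finite log2 fold changes, one per gene.
#' @param caseMean,controlMean optional pseudo-count-free group means.
#' @param case,control contrasted group labels.
#' @param pseudo pseudo-count used (positive).
#' @param feature `"gene"`, `"intron"` or `"exon"`.
#' @export
FoldChangeTable <- function(geneId, log2fc, caseMean = NA_real_,
                            controlMean = NA_real_, case = "case",
                            control = "control", pseudo = 0.1,
                            feature = "gene") {
  df <- DataFrame(gene_id = as.character(geneId),
                  case_mean = rep_len(as.numeric(caseMean), length(geneId)),
                  control_mean = rep_len(as.numeric(controlMean), length(geneId)),
                  log2fc = as.numeric(log2fc))
  rownames(df) <- df$gene_id
  new("FoldChangeTable", df, caseGroup = case, controlGroup = control,
      pseudo = pseudo, feature = feature)
}

setMethod("show", "FoldChangeTable", function(object) {
  cat(sprintf("FoldChangeTable (%s): %s vs %s, pseudo = %g, %d features\n",
              object@feature, object@caseGroup, object@controlGroup,
              object@pseudo, nrow(object)))
  callNextMethod()
})

## ---------------------------------------------------------------------------
## ShiftTestResult
## ---------------------------------------------------------------------------

#' Result of a distribution-shift (Mann-Whitney) comparison
#'
#' Holds the U statistic, p-value, medians and the two empirical CDFs for a
#' comparison of one value set (e.g. fold changes of NMD-target genes, or of
#' introns) against a background distribution.
#'
#' @slot setName label of the foreground set.
#' @slot nSet,nBackground sample sizes.
#' @slot nRequested number of identifiers requested before intersection with
#'   the measured features (equals `nSet` for non-gene-set comparisons).
#' @slot U Mann-Whitney U statistic of the set relative to the background.
#' @slot pValue p-value under the selected alternative.
#' @slot alternative `"two.sided"`, `"greater"` or `"less"`.
#' @slot medianSet,medianBackground,medianShift medians and their difference.
#' @slot ecdfSet,ecdfBackground data frames of sorted `(x, F)` pairs.
#' @export
setClass("ShiftTestResult",
         representation(setName = "character", nSet = "integer",
                        nBackground = "integer", nRequested = "integer",
                        U = "numeric", pValue = "numeric",
                        alternative = "character",
                        medianSet = "numeric", medianBackground = "numeric",
                        medianShift = "numeric",
                        ecdfSet = "data.frame", ecdfBackground = "data.frame"))

setValidity("ShiftTestResult", function(object) {
  msg <- character()
  if (object@U < 0 || object@U > object@nSet * as.numeric(object@nBackground))
    msg <- c(msg, "U must lie in [0, nSet * nBackground]")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in (0, 1]")
  for (nm in c("ecdfSet", "ecdfBackground")) {
    e <- slot(object, nm)
    if (!all(c("x", "F") %in% colnames(e)))
      msg <- c(msg, sprintf("%s must have columns x, F", nm))
    else if (nrow(e) && (is.unsorted(e$F) || e$F[nrow(e)] != 1))
      msg <- c(msg, sprintf("%s must be nondecreasing and end at 1", nm))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ShiftTestResult", function(object) {
  cat(sprintf("ShiftTestResult '%s': n = %d vs %d background\n",
              object@setName, object@nSet, object@nBackground))
  if (object@nRequested != object@nSet)
    cat(sprintf("  (%d of %d requested identifiers found)\n",
                object@nSet, object@nRequested))
  cat(sprintf("  median %0.4g vs %0.4g (shift %+0.4g)\n",
              object@medianSet, object@medianBackground, object@medianShift))
  cat(sprintf("  Mann-Whitney U = %g, %s p = %.4g\n",
              object@U, object@alternative, object@pValue))
})

## ---------------------------------------------------------------------------
## QpcrPlate
## ---------------------------------------------------------------------------

#' RT-qPCR plate of Ct values
#'
#' Well-level Ct measurements with the reference (housekeeping) target and
#' control condition recorded.  `wells` has columns `sample_id`, `condition`,
#' `target`, `replicate` (technical replicate index) and `ct`.
#'
#' @slot wells data frame of wells.
#' @slot referenceTarget internal-control target, default `"GAPDH"`.
#' @slot controlCondition condition to which fold changes are referenced.
#' @export
setClass("QpcrPlate",
         representation(wells = "data.frame", referenceTarget = "character",
                        controlCondition = "character"))

setValidity("QpcrPlate", function(object) {
  msg <- character()
  need <- c("sample_id", "condition", "target", "replicate", "ct")
  if (!all(need %in% colnames(object@wells)))
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  if (any(!is.finite(object@wells$ct)))
    msg <- c(msg, "all Ct values must be finite")
  if (length(object@referenceTarget) != 1L)
    msg <- c(msg, "referenceTarget must be a single string")
  if (length(object@controlCondition) != 1L)
    msg <- c(msg, "controlCondition must be a single string")
  if (length(msg)) msg else TRUE
})

#' @rdname QpcrPlate-class
#' @param wells data frame with columns `sample_id`, `condition`, `target`,
#'   `replicate`, `ct`.
#' @param referenceTarget housekeeping target used for delta-Ct normalisation.
#' @param controlCondition control condition (e.g. `"GFP"`, `"DMSO"`).
#' @export
QpcrPlate <- function(wells, referenceTarget = "GAPDH", controlCondition) {
  wells <- as.data.frame(wells)
  wells$ct <- as.numeric(wells$ct)
  obj <- new("QpcrPlate", wells = wells,
             referenceTarget = as.character(referenceTarget),
             controlCondition = as.character(controlCondition))
  out <- wells$ct < 5 | wells$ct > 40
  if (any(out))
    warning(sum(out), " Ct value(s) outside the typical 5-40 cycle range")
  obj
}

#' Read a qPCR plate from CSV
#'
#' @param path CSV with columns `sample_id`, `condition`, `target`,
#'   `replicate`, `ct`.
#' @inheritParams QpcrPlate
#' @return A [QpcrPlate-class].
#' @export
readQpcrPlate <- function(path, referenceTarget = "GAPDH", controlCondition) {
  QpcrPlate(utils::read.csv(path, stringsAsFactors = FALSE),
            referenceTarget = referenceTarget,
            controlCondition = controlCondition)
}

#' @describeIn QpcrPlate-class well-level data frame.
#' @param object a `QpcrPlate`.
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))

#' @export
setMethod("wells", "QpcrPlate", function(object) object@wells)

setMethod("show", "QpcrPlate", function(object) {
  w <- object@wells
  cat(sprintf("QpcrPlate: %d wells, %d samples, %d targets, %d conditions\n",
              nrow(w), length(unique(w$sample_id)), length(unique(w$target)),
              length(unique(w$condition))))
  cat(sprintf("  reference target: %s; control condition: %s\n",
              object@referenceTarget, object@controlCondition))
})

## ---------------------------------------------------------------------------
## ZeroInterceptFit
## ---------------------------------------------------------------------------

#' Least-squares line through the origin
#'
#' Fit of `y = beta * x` with `beta = sum(x*y) / sum(x^2)`.  In the
#' dose-response decomposition, `x` is the measured translational repression
#' `-log2(activity)` and `y` the log2 fold change of an NMD-target transcript,
#' so `beta` is the per-unit-repression accumulation of the target.
#'
#' @slot compound,target labels (may be `NA`).
#' @slot slope the fitted beta.
#' @slot se standard error of beta, `sqrt(RSS / (n - 1) / sum(x^2))`.
#' @slot rss residual sum of squares.
#' @slot n number of points.
#' @slot x,y the fitted data (kept for bootstrap resampling).
#' @export
setClass("ZeroInterceptFit",
         representation(compound = "character", target = "character",
                        slope = "numeric", se = "numeric", rss = "numeric",
                        n = "integer", x = "numeric", y = "numeric"))

setValidity("ZeroInterceptFit", function(object) {
  msg <- character()
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (object@n < 2L)
    msg <- c(msg, "at least two points are required")
  if (!is.finite(object@slope))
    msg <- c(msg, "slope must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ZeroInterceptFit", function(object) {
  lab <- paste(stats::na.omit(c(object@compound, object@target)), collapse = " / ")
  cat(sprintf("ZeroInterceptFit%s: beta = %.4g (se %.3g), n = %d, RSS = %.4g\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              object@slope, object@se, object@n, object@rss))
})
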