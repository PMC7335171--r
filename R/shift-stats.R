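#' Empirical cumulative distribution function as a step table
#'
#' Returns the right-continuous ECDF of a numeric vector as sorted `(x, F)`
#' pairs: `F` at each distinct value is the fraction of observations less than
#' or equal to it, so without ties `F` rises by exactly `1/N` per step and
#' reaches 1 at the maximum.
#'
#' @param values numeric vector with at least one finite value.
#' @return data frame with columns `x` (distinct sorted values) and `F`.
#' @export
ecdfTable <- function(values) {
  values <- values[is.finite(values)]
  .stopIfNot(length(values) >= 1L, "at least one finite value is required")
  x <- sort(unique(values))
  data.frame(x = x, F = stats::ecdf(values)(x))
}

#' Mann-Whitney U test
#'
#' Computes the U statistic of `x` relative to `y` using midranks for ties.
#' The p-value is exact (tail of the null U distribution) when there are no
#' ties and `length(x) * length(y) <= exactLimit`; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' `alternative = "greater"` tests whether `x` tends to exceed `y`.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exactLimit use the exact null distribution when `n_x * n_y` is at
#'   most this and there are no ties (default 400).
#' @return list with `U`, `p.value`, `alternative`, `method` (`"exact"` or
#'   `"normal"`), `nX`, `nY`.  When every value in both samples is identical
#'   the test is degenerate: `p.value = 1` with a warning.
#' @export
mannWhitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                        exactLimit = 400) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  .stopIfNot(length(x) >= 1L && length(y) >= 1L && all(is.finite(c(x, y))),
             "both samples must contain at least one finite value")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  method <- if (!ties && n1 * n2 <= exactLimit) "exact" else "normal"

  if (method == "exact") {
    pGreater <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    pLess <- stats::pwilcox(U, n1, n2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pGreater, pLess)),
                greater = pGreater,
                less = pLess)
  } else {
    tieCounts <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tieCounts^3 - tieCounts) / (n * (n - 1)))
    if (sigma2 <= 0) {
      warning("all values identical across both samples; degenerate test")
      return(list(U = U, p.value = 1, alternative = alternative,
                  method = "degenerate", nX = n1, nY = n2))
    }
    mu <- n1 * n2 / 2
    z <- U - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- (z - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * stats::pnorm(-abs(z))),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
  }
  list(U = U, p.value = max(p, .Machine$double.xmin),
       alternative = alternative, method = method, nX = n1, nY = n2)
}

.shiftResult <- function(setName, setVals, bgVals, alternative,
                         nRequested = length(setVals), exactLimit = 400) {
  mw <- mannWhitney(setVals, bgVals, alternative = alternative,
                    exactLimit = exactLimit)
  new("ShiftTestResult", setName = setName,
      nSet = length(setVals), nBackground = length(bgVals),
      nRequested = as.integer(nRequested),
      U = mw$U, pValue = mw$p.value, alternative = alternative,
      medianSet = stats::median(setVals),
      medianBackground = stats::median(bgVals),
      medianShift = stats::median(setVals) - stats::median(bgVals),
      ecdfSet = ecdfTable(setVals), ecdfBackground = ecdfTable(bgVals))
}

#' Intron-retention summary for a group contrast
#'
#' Summarises a table of intronic read-density fold changes: the median log2
#' fold change (and its linear-scale fold change), a one-sided Mann-Whitney
#' test of the intron fold changes against a reference distribution, and
#' presentational histogram bins.  The natural reference is the same
#' contrast's exonic (or gene-level) fold changes, so that a global shift of
#' intron densities beyond any overall expression shift is detected.
#'
#' @param fc a [FoldChangeTable-class] of intron fold changes (>= 10 rows).
#' @param reference a [FoldChangeTable-class] or numeric vector of reference
#'   log2 fold changes (typically the exonic fold changes of the same
#'   contrast).
#' @param alternative test direction, default `"greater"` (introns shifted
#'   up relative to the reference).
#' @param bins,range histogram layout: `bins` equal-width bins over `range`
#'   log2 units with out-of-range values clipped to the ends (default 50 bins
#'   on \[-4, 4\]).
#' @return list with `result` (a [ShiftTestResult-class]), `medianLog2fc`,
#'   `medianFoldChange` (`2^medianLog2fc`) and `histogram` (data frame of bin
#'   midpoints and counts for both distributions).
#' @export
intronRetentionSummary <- function(fc, reference,
                                   alternative = c("greater", "two.sided", "less"),
                                   bins = 50, range = c(-4, 4)) {
  alternative <- match.arg(alternative)
  vals <- fc$log2fc
  .stopIfNot(length(vals) >= 10L, "at least 10 introns are required")
  refVals <- if (methods::is(reference, "FoldChangeTable")) reference$log2fc
             else as.numeric(reference)
  .stopIfNot(length(refVals) >= 1L, "reference distribution is empty")
  res <- .shiftResult("introns", vals, refVals, alternative)
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  clip <- function(v) pmin(pmax(v, range[1]), range[2])
  hist <- data.frame(
    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    count_intron = as.integer(table(cut(clip(vals), breaks, include.lowest = TRUE))),
    count_reference = as.integer(table(cut(clip(refVals), breaks,
                                           include.lowest = TRUE))))
  list(result = res, medianLog2fc = stats::median(vals),
       medianFoldChange = 2^stats::median(vals), histogram = hist)
}

#' Gene-set distribution-shift test
#'
#' Compares the fold changes of a gene set's members against background genes
#' with a Mann-Whitney U test (two-sided by default) and returns both
#' empirical CDFs for plotting.  Being a rank test, the result is invariant
#' under any strictly monotone transform of the fold changes.
#'
#' @param fc a [FoldChangeTable-class] (typically gene-level mRNA abundance
#'   fold changes).
#' @param geneSet a [GeneSet-class].
#' @param alternative test direction, default `"two.sided"`.
#' @param background `"complement"` (default; all measured genes not in the
#'   set) or `"all"` (every measured gene, set members included).
#' @return A [ShiftTestResult-class]; errors if fewer than 2 set members are
#'   present in `fc`, listing the missing identifiers.
#' @export
genesetShiftTest <- function(fc, geneSet,
                             alternative = c("two.sided", "greater", "less"),
                             background = c("complement", "all")) {
  alternative <- match.arg(alternative)
  background <- match.arg(background)
  vals <- stats::setNames(fc$log2fc, fc$gene_id)
  found <- intersect(geneSet@members, names(vals))
  if (length(found) < 2L) {
    missing <- setdiff(geneSet@members, names(vals))
    stop("fewer than 2 members of '", geneSet@name,
         "' are present in the fold-change table; missing: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  }
  bgIds <- if (background == "complement") setdiff(names(vals), found)
           else names(vals)
  .shiftResult(geneSet@name, unname(vals[found]), unname(vals[bgIds]),
               alternative, nRequested = length(geneSet@members))
}

#' Per-gene group comparison of control-normalised expression
#'
#' For each requested gene, divides every sample's gene RPM (exonic reads) by
#' the control-group mean — so the control group's normalised mean is exactly
#' 1 — and performs a two-sided unpaired t-test between the groups.  The
#' classical pooled-variance test is the default; set `welch = TRUE` for the
#' Welch form.  Box statistics (median, quartiles, whiskers at 1.5 x IQR) are
#' reported per group.
#'
#' @param object a [FeatureCountExperiment-class] (densities computed on the
#'   fly if absent).
#' @param genes character vector of gene identifiers to compare.
#' @param case,control group labels (each needs >= 2 samples).
#' @param welch use the Welch unequal-variance t-test instead of pooled.
#' @return data frame with one row per gene (t, df, p, group means and box
#'   stats); genes with a zero control mean are skipped with a warning.  The
#'   control-normalised value matrix is attached as `attr(, "normalized")`.
#' @export
perGeneGroupCompare <- function(object, genes, case, control, welch = FALSE) {
  grp <- sampleGroups(object)
  for (g in c(case, control))
    .stopIfNot(g %in% grp, "unknown group: ", g)
  .stopIfNot(sum(grp == case) >= 2L && sum(grp == control) >= 2L,
             "at least 2 samples per group are required")
  if (!"rpm" %in% assayNames(object))
    object <- computeDensity(object)
  sel <- featureType(object) == "exon"
  rpm <- assay(object, "rpm")[sel, , drop = FALSE]
  rownames(rpm) <- geneId(object)[sel]
  missing <- setdiff(genes, rownames(rpm))
  .stopIfNot(length(missing) == 0,
             "genes not found: ", paste(missing, collapse = ", "))

  boxStats <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    c(q1 = q[1], median = q[2], q3 = q[3], whisker_lo = lo, whisker_hi = hi)
  }

  rows <- list()
  normMat <- matrix(NA_real_, nrow = 0, ncol = ncol(rpm),
                    dimnames = list(NULL, colnames(rpm)))
  for (g in genes) {
    ctrlVals <- rpm[g, grp == control]
    if (mean(ctrlVals) == 0) {
      warning("gene ", g, " skipped: zero control-group mean")
      next
    }
    norm <- rpm[g, ] / mean(ctrlVals)
    caseN <- norm[grp == case]; ctrlN <- norm[grp == control]
    tt <- tryCatch(stats::t.test(caseN, ctrlN, var.equal = !welch),
                   error = function(e) {
                     # zero within-group spread: take the limiting t
                     meanDiff <- mean(caseN) - mean(ctrlN)
                     t <- if (meanDiff == 0) 0 else sign(meanDiff) * Inf
                     list(statistic = c(t = t),
                          parameter = c(df = length(caseN) + length(ctrlN) - 2),
                          p.value = if (meanDiff == 0) 1 else 0)
                   })
    bc <- boxStats(caseN); bk <- boxStats(ctrlN)
    rows[[g]] <- data.frame(
      gene_id = g, n_case = length(caseN), n_control = length(ctrlN),
      mean_case = mean(caseN), mean_control = mean(ctrlN),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      t(stats::setNames(bc, paste0(names(bc), "_case"))),
      t(stats::setNames(bk, paste0(names(bk), "_control"))))
    normMat <- rbind(normMat, norm)
    rownames(normMat)[nrow(normMat)] <- g
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  attr(out, "normalized") <- normMat
  out
}
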