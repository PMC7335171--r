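#' Read a dose-response table
#'
#' @param path CSV with columns `compound`, `concentration`, `conc_units`,
#'   `replicate`, `luc_activity`, `luc_mrna`, `target`, `target_abundance`
#'   (one row per target per treated well; luciferase readings repeat across a
#'   well's target rows).
#' @return validated data frame.
#' @export
readDoseResponse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "concentration", "conc_units", "replicate",
            "luc_activity", "luc_mrna", "target", "target_abundance")
  .stopIfNot(all(need %in% colnames(df)),
             "dose-response table needs columns: ", paste(need, collapse = ", "))
  .stopIfNot(all(df$luc_activity > 0) && all(df$luc_mrna > 0) &&
               all(df$target_abundance > 0),
             "all measurements must be positive")
  df
}

.isControlPoint <- function(df) {
  df$concentration == 0 |
    tolower(df$compound) %in% c("dmso", "vehicle", "control", "untreated")
}

#' Translational activity from a luciferase reporter
#'
#' Activity of each point is the ratio of luciferase activity to luciferase
#' mRNA abundance, normalised so that the mean over vehicle-control points
#' (concentration 0 or a vehicle compound label such as `"DMSO"`) is exactly
#' 1.  Repression is `-log2(activity)`, expected to be >= 0 for translation
#' inhibitors.
#'
#' @param df dose-response data frame (see [readDoseResponse()]); rows are
#'   deduplicated to one per (compound, concentration, replicate) well.
#' @return data frame of points with `is_control`, `activity` and
#'   `repression` columns.
#' @export
translationActivity <- function(df) {
  pts <- unique(df[c("compound", "concentration", "replicate",
                     "luc_activity", "luc_mrna")])
  pts$is_control <- .isControlPoint(pts)
  .stopIfNot(any(pts$is_control), "no vehicle-control point found")
  ratio <- pts$luc_activity / pts$luc_mrna
  pts$activity <- ratio / mean(ratio[pts$is_control])
  pts$repression <- -log2(pts$activity)
  pts[order(pts$compound, pts$concentration, pts$replicate), ]
}

#' Fit a least-squares line through the origin
#'
#' `beta = sum(x*y) / sum(x^2)`, with standard error
#' `sqrt(RSS / (n - 1) / sum(x^2))`.  In the dose-response decomposition `x`
#' is the measured translational repression (`-log2` activity) and `y` the
#' log2 fold change of an NMD-target transcript.
#'
#' @param x,y equal-length numeric vectors (n >= 2); `sum(x^2)` must be
#'   positive.
#' @param compound,target optional labels stored in the fit.
#' @return A [ZeroInterceptFit-class].
#' @export
fitZeroIntercept <- function(x, y, compound = NA_character_,
                             target = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  .stopIfNot(length(x) == length(y), "x and y must have equal length")
  .stopIfNot(length(x) >= 2L && all(is.finite(c(x, y))),
             "at least two finite points are required")
  sxx <- sum(x^2)
  .stopIfNot(sxx > 0, "all x are zero; slope is undefined")
  beta <- sum(x * y) / sxx
  rss <- sum((y - beta * x)^2)
  methods::new("ZeroInterceptFit", compound = as.character(compound),
               target = as.character(target), slope = beta,
               se = sqrt(rss / (length(x) - 1) / sxx), rss = rss,
               n = length(x), x = x, y = y)
}

#' Fraction of NMD-target accumulation explained by translational repression
#'
#' The slope ratio `F = 100 * beta_PR / beta_CHX` (percent): per unit of
#' measured translational repression, how much NMD-target accumulation the
#' test compound produces relative to the pure translation-elongation
#' inhibitor cycloheximide.  `F` near 100% means the compound's effect on the
#' target is fully accounted for by its effect on translation.  `F` is
#' invariant to rescaling both fits' x-axes by a common positive factor.
#'
#' @param fitPr zero-intercept fit for the test compound (e.g. PR20).
#' @param fitChx zero-intercept fit for the CHX reference (|slope| must
#'   exceed `tol`).
#' @param nBoot if > 0, bootstrap the points of both fits (with replacement,
#'   `nBoot` draws) for a percentile confidence interval.
#' @param seed optional integer seed for the bootstrap.
#' @param level confidence level for the bootstrap interval (default 0.95).
#' @param tol minimum |beta_CHX| (default 1e-9).
#' @return one-row data frame: `target`, `fraction_pct`, `slope_pr`, `se_pr`,
#'   `slope_chx`, `se_chx`, and `ci_lower`/`ci_upper`/`n_boot` when
#'   bootstrapped.
#' @export
fractionExplained <- function(fitPr, fitChx, nBoot = 0, seed = NULL,
                              level = 0.95, tol = 1e-9) {
  .stopIfNot(methods::is(fitPr, "ZeroInterceptFit") &&
               methods::is(fitChx, "ZeroInterceptFit"),
             "both arguments must be ZeroInterceptFit objects")
  if (!is.na(fitPr@target) && !is.na(fitChx@target))
    .stopIfNot(fitPr@target == fitChx@target,
               "fits are for different targets: ", fitPr@target, " vs ",
               fitChx@target)
  .stopIfNot(abs(fitChx@slope) >= tol,
             "reference (CHX) slope is numerically zero; fraction undefined")
  out <- data.frame(
    target = if (!is.na(fitPr@target)) fitPr@target else fitChx@target,
    fraction_pct = 100 * fitPr@slope / fitChx@slope,
    slope_pr = fitPr@slope, se_pr = fitPr@se,
    slope_chx = fitChx@slope, se_chx = fitChx@se,
    ci_lower = NA_real_, ci_upper = NA_real_, n_boot = as.integer(nBoot))
  if (nBoot > 0) {
    draw <- function() {
      bSlope <- function(f) {
        i <- sample.int(f@n, f@n, replace = TRUE)
        sum(f@x[i] * f@y[i]) / sum(f@x[i]^2)
      }
      sChx <- bSlope(fitChx)
      if (abs(sChx) < tol) return(NA_real_)
      100 * bSlope(fitPr) / sChx
    }
    boot <- function() vapply(seq_len(nBoot), function(i) draw(), numeric(1))
    fs <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
    qs <- stats::quantile(fs, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    out$ci_lower <- qs[1]; out$ci_upper <- qs[2]
  }
  out
}

#' Full dose-response decomposition pipeline
#'
#' Chains [translationActivity()], per-target fold-change computation and
#' [fitZeroIntercept()] into per-target [fractionExplained()] results.  Target
#' abundances (already reference-normalised on input) are converted to log2
#' fold changes against the geometric mean of the vehicle-control points; the
#' x-axis is the measured repression of each treated point.  Control points
#' define the origin and are excluded from the fits.  By default all treated
#' points of a compound are pooled into one fit; `perReplicate = TRUE` fits
#' each replicate series separately and averages the slopes.
#'
#' @param df dose-response data frame (see [readDoseResponse()]).
#' @param targets targets to analyse (default: all in `df`).
#' @param referenceCompound compound treated as the pure
#'   translation-inhibition reference (matched case-insensitively; default
#'   `"CHX"`).
#' @param perReplicate fit per replicate then average slopes.
#' @param nBoot,seed bootstrap settings passed to [fractionExplained()]
#'   (pooled fits only).
#' @return list with `activity` (point table), `fits` (tidy data frame and a
#'   named list of [ZeroInterceptFit-class] objects in `attr(,"objects")`),
#'   `fractions` (per-target data frame) and `plotData` (per-point
#'   repression / log2 fold-change coordinates).
#' @export
doseResponsePipeline <- function(df, targets = NULL,
                                 referenceCompound = "CHX",
                                 perReplicate = FALSE, nBoot = 0,
                                 seed = NULL) {
  if (is.null(targets)) targets <- sort(unique(df$target))
  act <- translationActivity(df)
  treated <- act[!act$is_control, ]
  compounds <- unique(treated$compound)
  refIdx <- tolower(compounds) == tolower(referenceCompound)
  .stopIfNot(sum(refIdx) == 1L,
             "missing compound: reference '", referenceCompound,
             "' not found among treated points")
  .stopIfNot(length(compounds) == 2L,
             "missing compound: exactly one test compound and the '",
             referenceCompound, "' reference are required")
  for (cp in compounds)
    .stopIfNot(length(unique(treated$concentration[treated$compound == cp])) >= 2L,
               "compound ", cp, " needs >= 2 non-control concentrations")
  testCompound <- compounds[!refIdx]
  refCompound <- compounds[refIdx]

  key <- function(d) paste(d$compound, d$concentration, d$replicate)
  df$repression <- act$repression[match(key(df), key(act))]
  df$is_control <- .isControlPoint(df)

  fits <- list(); plotRows <- list(); fracRows <- list()
  for (tg in targets) {
    sub <- df[df$target == tg, , drop = FALSE]
    .stopIfNot(nrow(sub) > 0, "target not found: ", tg)
    ctrlAb <- sub$target_abundance[sub$is_control]
    .stopIfNot(length(ctrlAb) > 0, "no control points for target ", tg)
    sub$log2fc <- log2(sub$target_abundance) - mean(log2(ctrlAb))
    tr <- sub[!sub$is_control, ]
    plotRows[[tg]] <- tr[c("target", "compound", "concentration", "conc_units",
                           "replicate", "repression", "log2fc")]
    fitOne <- function(cp) {
      d <- tr[tr$compound == cp, ]
      if (!perReplicate)
        return(fitZeroIntercept(d$repression, d$log2fc, compound = cp,
                                target = tg))
      slopes <- vapply(split(d, d$replicate), function(r)
        sum(r$repression * r$log2fc) / sum(r$repression^2), numeric(1))
      f <- fitZeroIntercept(d$repression, d$log2fc, compound = cp,
                            target = tg)
      f@slope <- mean(slopes)
      f@se <- stats::sd(slopes) / sqrt(length(slopes))
      f@rss <- sum((d$log2fc - f@slope * d$repression)^2)
      f
    }
    fPr <- fitOne(testCompound)
    fChx <- fitOne(refCompound)
    fits[[paste(tg, testCompound, sep = ".")]] <- fPr
    fits[[paste(tg, refCompound, sep = ".")]] <- fChx
    fracRows[[tg]] <- fractionExplained(fPr, fChx,
                                        nBoot = if (perReplicate) 0 else nBoot,
                                        seed = seed)
  }
  fitDf <- do.call(rbind, lapply(fits, function(f)
    data.frame(target = f@target, compound = f@compound, slope = f@slope,
               se = f@se, rss = f@rss, n = f@n)))
  rownames(fitDf) <- NULL
  attr(fitDf, "objects") <- fits
  fractions <- do.call(rbind, fracRows)
  rownames(fractions) <- NULL
  plotData <- do.call(rbind, plotRows)
  rownames(plotData) <- NULL
  list(activity = act, fits = fitDf, fractions = fractions,
       plotData = plotData)
}
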