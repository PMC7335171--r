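#' Collapse technical qPCR replicates
#'
#' Averages Ct values across technical replicates of each
#' (sample, condition, target) well group.  A within-well spread above
#' `spreadWarn` cycles (default 0.5) triggers a warning, since technical
#' replicates of a clean reaction should agree closely.
#'
#' @param plate a [QpcrPlate-class].
#' @param spreadWarn warn when `max(ct) - min(ct)` within a well group exceeds
#'   this many cycles.
#' @return A [QpcrPlate-class] with one well (replicate index 1) per group.
#' @export
averageTechnicalReplicates <- function(plate, spreadWarn = 0.5) {
  w <- wells(plate)
  key <- interaction(w$sample_id, w$condition, w$target, drop = TRUE)
  spread <- tapply(w$ct, key, function(v) max(v) - min(v))
  if (any(spread > spreadWarn))
    warning(sum(spread > spreadWarn), " well group(s) with technical-replicate ",
            "Ct spread > ", spreadWarn, " cycles")
  agg <- stats::aggregate(ct ~ sample_id + condition + target, data = w,
                          FUN = mean)
  agg$replicate <- 1L
  agg <- agg[order(agg$sample_id, agg$condition, agg$target),
             c("sample_id", "condition", "target", "replicate", "ct")]
  methods::new("QpcrPlate", wells = agg,
               referenceTarget = plate@referenceTarget,
               controlCondition = plate@controlCondition)
}

#' One-sample ratio t-test on log2 fold changes
#'
#' The "ratio t-test": a two-sided one-sample Student t-test of per-replicate
#' log2 fold changes against 0, i.e. of the hypothesis that the expression
#' ratio is 1.  Ratios are tested on the log scale, where fold changes are
#' symmetric and closer to normal.
#'
#' @param log2fc numeric vector of per-replicate log2 fold changes (n >= 2,
#'   non-zero spread).
#' @return list with `t`, `df` and `p.value`.
#' @export
ratioTTest <- function(log2fc) {
  log2fc <- as.numeric(log2fc)
  .stopIfNot(length(log2fc) >= 2L && all(is.finite(log2fc)),
             "at least two finite log2 fold changes are required")
  .stopIfNot(stats::sd(log2fc) > 0, "degenerate replicate set (zero spread)")
  tt <- stats::t.test(log2fc, mu = 0, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Delta-delta-Ct relative expression
#'
#' Technical replicates are collapsed first; then, per biological replicate
#' (sample): `dCt = Ct(target) - Ct(reference)`;
#' `ddCt = dCt - mean(dCt over control-condition samples)`; the fold change is
#' `2^(-ddCt)`, assuming 100% amplification efficiency (a doubling per cycle;
#' override via `efficiency` as the per-cycle amplification factor).  Summary
#' fold changes are geometric means of per-replicate fold changes, which makes
#' the control condition's summary fold change exactly 1, and p-values come
#' from the two-sided ratio t-test ([ratioTTest()]) on per-replicate log2 fold
#' changes.
#'
#' @param plate a [QpcrPlate-class].
#' @param efficiency per-cycle amplification factor, default 2 (100%
#'   efficiency).
#' @return data frame with one row per (condition, target): `n`,
#'   `mean_log2fc`, `sd_log2fc`, `fold_change`, `p_value` (`NA` where fewer
#'   than 2 replicates or zero spread).  Per-replicate values are attached as
#'   `attr(, "replicates")`.
#' @export
relativeExpression <- function(plate, efficiency = 2) {
  avg <- averageTechnicalReplicates(plate)
  w <- wells(avg)
  ref <- plate@referenceTarget
  ctrl <- plate@controlCondition
  .stopIfNot(ctrl %in% w$condition,
             "control condition '", ctrl, "' not present on the plate")

  refCt <- w[w$target == ref, c("sample_id", "condition", "ct")]
  names(refCt)[3] <- "ref_ct"
  targets <- w[w$target != ref, , drop = FALSE]
  merged <- merge(targets, refCt, by = c("sample_id", "condition"))
  lost <- setdiff(unique(paste(targets$sample_id, targets$condition)),
                  unique(paste(merged$sample_id, merged$condition)))
  if (length(lost))
    stop("missing reference target '", ref, "' wells for sample(s): ",
         paste(lost, collapse = "; "))

  merged$delta_ct <- merged$ct - merged$ref_ct
  ctrlMean <- tapply(merged$delta_ct[merged$condition == ctrl],
                     merged$target[merged$condition == ctrl], mean)
  .stopIfNot(all(unique(merged$target) %in% names(ctrlMean)),
             "control condition lacks wells for some targets")
  merged$ddct <- merged$delta_ct - ctrlMean[merged$target]
  merged$log2fc <- -merged$ddct * log2(efficiency)
  merged$fold_change <- 2^merged$log2fc

  reps <- merged[order(merged$condition, merged$target, merged$sample_id),
                 c("sample_id", "condition", "target", "delta_ct", "ddct",
                   "log2fc", "fold_change")]
  split_key <- interaction(reps$condition, reps$target, drop = TRUE)
  summ <- do.call(rbind, lapply(split(reps, split_key), function(d) {
    p <- if (nrow(d) >= 2 && stats::sd(d$log2fc) > 0)
      ratioTTest(d$log2fc)$p.value else NA_real_
    data.frame(condition = d$condition[1], target = d$target[1], n = nrow(d),
               mean_log2fc = mean(d$log2fc), sd_log2fc = stats::sd(d$log2fc),
               fold_change = 2^mean(d$log2fc), p_value = p)
  }))
  summ <- summ[order(summ$condition, summ$target), , drop = FALSE]
  rownames(summ) <- NULL
  attr(summ, "replicates") <- reps
  attr(summ, "referenceTarget") <- ref
  attr(summ, "controlCondition") <- ctrl
  summ
}

#' Nuclear fraction of transcripts from fractionated qPCR
#'
#' From matched nuclear and cytoplasmic plates (same samples, conditions and
#' targets), technical replicates are collapsed, relative abundance in each
#' fraction is taken as `2^(-Ct)` (equal fraction volumes assumed, no
#' cross-fraction normaliser — compartment-restricted transcripts such as U1
#' snRNA and GAPDH mRNA act as internal controls), and the per-replicate
#' nuclear fraction is `A_nuc / (A_nuc + A_cyt)`, always in \[0, 1\] and
#' monotone decreasing in the nuclear Ct.  Conditions are compared to the
#' control condition per target by a two-sided unpaired t-test on the
#' per-replicate fractions.
#'
#' @param plateNuc,plateCyt [QpcrPlate-class] objects for the nuclear and
#'   cytoplasmic fractions (the control condition of `plateNuc` is used).
#' @param welch use Welch's t-test instead of the pooled-variance form.
#' @return data frame per (condition, target) with mean, sd, n and `p_value`
#'   vs the control condition (`NA` for the control rows); per-replicate
#'   fractions attached as `attr(, "replicates")`.  Transcripts present in
#'   only one fraction are skipped with a warning.
#' @export
nuclearFraction <- function(plateNuc, plateCyt, welch = FALSE) {
  nw <- wells(averageTechnicalReplicates(plateNuc))
  cw <- wells(averageTechnicalReplicates(plateCyt))
  names(nw)[names(nw) == "ct"] <- "ct_nuc"
  names(cw)[names(cw) == "ct"] <- "ct_cyt"
  m <- merge(nw[c("sample_id", "condition", "target", "ct_nuc")],
             cw[c("sample_id", "condition", "target", "ct_cyt")],
             by = c("sample_id", "condition", "target"))
  dropped <- union(setdiff(unique(nw$target), unique(cw$target)),
                   setdiff(unique(cw$target), unique(nw$target)))
  if (length(dropped))
    warning("target(s) present in only one fraction skipped: ",
            paste(dropped, collapse = ", "))
  .stopIfNot(nrow(m) > 0, "no matched wells between the two fractions")

  aNuc <- 2^(-m$ct_nuc); aCyt <- 2^(-m$ct_cyt)
  m$nuclear_fraction <- aNuc / (aNuc + aCyt)
  ctrl <- plateNuc@controlCondition
  reps <- m[order(m$condition, m$target, m$sample_id), ]
  summ <- do.call(rbind, lapply(
    split(reps, interaction(reps$condition, reps$target, drop = TRUE)),
    function(d) {
      p <- NA_real_
      if (d$condition[1] != ctrl) {
        ctrlVals <- reps$nuclear_fraction[reps$condition == ctrl &
                                            reps$target == d$target[1]]
        if (length(ctrlVals) >= 2 && nrow(d) >= 2 &&
            (stats::sd(c(d$nuclear_fraction, ctrlVals)) > 0))
          p <- stats::t.test(d$nuclear_fraction, ctrlVals,
                             var.equal = !welch)$p.value
      }
      data.frame(condition = d$condition[1], target = d$target[1],
                 n = nrow(d), mean_fraction = mean(d$nuclear_fraction),
                 sd_fraction = stats::sd(d$nuclear_fraction), p_value = p)
    }))
  summ <- summ[order(summ$condition, summ$target), , drop = FALSE]
  rownames(summ) <- NULL
  attr(summ, "replicates") <- reps
  summ
}
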