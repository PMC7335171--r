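#' Neuronal survival fraction
#'
#' `S = n_t48 / n_t0`: the fraction of labelled neurons present before
#' treatment that are still present 48 h after.  Values slightly above 1 are
#' possible through counting error and produce a warning.
#'
#' @param nT0 positive count(s) of neurons before treatment.
#' @param nT48 non-negative count(s) after 48 h.
#' @return numeric vector of survival fractions.
#' @export
survivalFraction <- function(nT0, nT48) {
  .stopIfNot(all(nT0 > 0), "n_t0 must be positive")
  .stopIfNot(all(nT48 >= 0), "n_t48 must be non-negative")
  if (any(nT48 > nT0))
    warning("n_t48 exceeds n_t0 for ", sum(nT48 > nT0), " record(s)")
  nT48 / nT0
}

#' Relative survival versus a control condition
#'
#' Pairs each condition with the control within every independent experiment,
#' forms the per-experiment survival ratio `S_cond / S_control`, and reports
#' the mean percent change `100 * (mean ratio - 1)` (the headline
#' "average increase" aggregation) alongside the ratio-of-means alternative.
#' Significance is a two-sided paired t-test on the per-experiment log ratios.
#' Experiments lacking either member of a pair are excluded with a warning.
#'
#' @param records data frame with columns `condition`, `experiment_id`,
#'   `n_t0`, `n_t48` (one row per condition per experiment).
#' @param control control condition label.
#' @return data frame per non-control condition: `n_pairs`, `mean_ratio`,
#'   `pct_change` (mean of per-experiment ratios), `pct_change_ratio_of_means`,
#'   `t`, `df`, `p_value`.  When all ratios are identical the t-test is
#'   degenerate: p is 1 if the ratios equal 1, otherwise `NA`.
#' @export
relativeSurvival <- function(records, control) {
  .stopIfNot(control %in% records$condition, "unknown control condition: ",
             control)
  records$S <- survivalFraction(records$n_t0, records$n_t48)
  ctrl <- records[records$condition == control,
                  c("experiment_id", "S")]
  names(ctrl)[2] <- "S_control"
  conds <- setdiff(unique(records$condition), control)
  out <- do.call(rbind, lapply(conds, function(cond) {
    d <- merge(records[records$condition == cond, ], ctrl,
               by = "experiment_id")
    dropped <- setdiff(records$experiment_id[records$condition == cond],
                       d$experiment_id)
    if (length(dropped))
      warning("condition ", cond, ": unpaired experiment(s) excluded: ",
              paste(dropped, collapse = ", "))
    .stopIfNot(nrow(d) >= 1L, "no paired experiments for condition ", cond)
    ratio <- d$S / d$S_control
    logRatio <- log(ratio)
    if (nrow(d) >= 2 && stats::sd(logRatio) > 0) {
      tt <- stats::t.test(logRatio, mu = 0)
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    } else if (all(ratio == 1)) {
      t <- 0; df <- nrow(d) - 1; p <- 1
    } else {
      t <- NA_real_; df <- NA_real_; p <- NA_real_
    }
    data.frame(condition = cond, n_pairs = nrow(d),
               mean_ratio = mean(ratio),
               pct_change = 100 * (mean(ratio) - 1),
               pct_change_ratio_of_means = 100 * (mean(d$S) / mean(d$S_control) - 1),
               t = t, df = df, p_value = p)
  }))
  rownames(out) <- NULL
  out
}

#' Stress-granule-positive cell fractions with group tests
#'
#' Per experiment, the SG-positive fraction is `n_sg_positive /
#' n_transfected`.  Conditions are summarised as mean +/- sd over experiments
#' and compared with the control condition by a two-sided unpaired t-test on
#' the untransformed per-experiment fractions (pooled variance by default;
#' `welch = TRUE` for the Welch form, `arcsine = TRUE` to test
#' variance-stabilised `asin(sqrt(p))` values instead).
#'
#' @param records data frame with columns `condition`, `experiment_id`,
#'   `n_transfected` (positive), `n_sg_positive` (at most `n_transfected`).
#' @param control control condition label.
#' @param welch use Welch's t-test.
#' @param arcsine test arcsine-square-root transformed fractions.
#' @return data frame per condition (`mean_fraction`, `sd_fraction`, `n`,
#'   `p_value` vs control; `NA` for the control row); per-experiment fractions
#'   attached as `attr(, "replicates")`.
#' @export
sgPositiveStats <- function(records, control, welch = FALSE, arcsine = FALSE) {
  .stopIfNot(all(records$n_transfected > 0), "n_transfected must be positive")
  .stopIfNot(all(records$n_sg_positive >= 0 &
                   records$n_sg_positive <= records$n_transfected),
             "n_sg_positive must lie in [0, n_transfected]")
  .stopIfNot(control %in% records$condition, "unknown control condition: ",
             control)
  records$fraction <- records$n_sg_positive / records$n_transfected
  tVal <- if (arcsine) function(p) asin(sqrt(p)) else identity
  ctrlVals <- records$fraction[records$condition == control]
  out <- do.call(rbind, lapply(split(records, records$condition), function(d) {
    p <- NA_real_
    if (d$condition[1] != control && nrow(d) >= 2 && length(ctrlVals) >= 2) {
      a <- tVal(d$fraction); b <- tVal(ctrlVals)
      p <- if (stats::sd(c(a, b)) > 0)
        stats::t.test(a, b, var.equal = !welch)$p.value else 1
    }
    data.frame(condition = d$condition[1], n = nrow(d),
               mean_fraction = mean(d$fraction),
               sd_fraction = stats::sd(d$fraction), p_value = p)
  }))
  rownames(out) <- NULL
  attr(out, "replicates") <- records[order(records$condition,
                                           records$experiment_id), ]
  out
}
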