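#' Simulate a two-group exon/intron count matrix with known shifts
#'
#' Generates the data structure behind intron-retention and gene-set shift
#' analyses: per-gene baseline expression drawn log-normally, counts drawn
#' negative-binomially (over-dispersed, as in bulk RNA-seq), a case group in
#' which every gene's intron counts are inflated by a gene-specific log-normal
#' factor with configurable median (intron retention), and a gene set whose
#' members' exonic counts are shifted by a configurable normal log2 effect
#' (NMD-target accumulation).  All per-gene factors are recorded in the truth
#' table.  Identical seeds reproduce the output bit-identically.
#'
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param nGenes,nSet number of genes and of gene-set members (`nSet <=
#'   nGenes`).
#' @param nPerGroup samples per group.
#' @param caseGroup,controlGroup group labels.
#' @param baselineMeanLog,baselineSdLog log-normal (natural-log) parameters of
#'   per-gene mean exonic counts.
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param intronFraction baseline intron read level as a fraction of the
#'   gene's exonic level.
#' @param intronShiftLog2,intronShiftSdLog2 per-gene case-group intron
#'   inflation: log2 factors drawn Normal(shift, sd), so the median factor is
#'   `2^intronShiftLog2`.
#' @param setShiftMeanLog2,setShiftSdLog2 per-gene case-group exonic shift for
#'   set members, Normal on the log2 scale.
#' @param libFactorSd log-normal spread of per-sample depth factors.
#' @return list with `experiment` (a [FeatureCountExperiment-class]),
#'   `sampleSheet`, `geneSet` (a [GeneSet-class]), `truth` (per-gene factors)
#'   and `config`.  Library sizes are set to each sample's expected baseline
#'   read total (depth factor times the unshifted transcriptome mass), so the
#'   injected per-gene factors are expressed directly in measured-density
#'   space rather than being diluted by the extra read mass they create.
#' @export
simulateCounts <- function(seed = 1, nGenes = 5000, nSet = 275,
                           nPerGroup = 8, caseGroup = "case",
                           controlGroup = "control",
                           baselineMeanLog = log(200), baselineSdLog = 1,
                           dispersion = 0.1, intronFraction = 0.15,
                           intronShiftLog2 = log2(2.1),
                           intronShiftSdLog2 = 0.25,
                           setShiftMeanLog2 = 0.5, setShiftSdLog2 = 0.25,
                           libFactorSd = 0.1) {
  .stopIfNot(nSet <= nGenes, "nSet must not exceed nGenes")
  config <- as.list(environment())
  withr::with_seed(seed, {
    geneIds <- sprintf("gene%05d", seq_len(nGenes))
    baseline <- stats::rlnorm(nGenes, baselineMeanLog, baselineSdLog)
    exonLen <- round(stats::runif(nGenes, 1000, 5000))
    intronLen <- round(stats::runif(nGenes, 2000, 10000))
    setIdx <- sort(sample.int(nGenes, nSet))
    intronFac <- stats::rnorm(nGenes, intronShiftLog2, intronShiftSdLog2)
    exonFac <- rep(0, nGenes)
    exonFac[setIdx] <- stats::rnorm(nSet, setShiftMeanLog2, setShiftSdLog2)

    nS <- 2 * nPerGroup
    group <- rep(c(caseGroup, controlGroup), each = nPerGroup)
    libFac <- stats::rlnorm(nS, 0, libFactorSd)
    isCase <- group == caseGroup
    rdraw <- function(mu) {
      if (dispersion > 0) stats::rnbinom(length(mu), mu = mu,
                                         size = 1 / dispersion)
      else stats::rpois(length(mu), mu)
    }
    counts <- matrix(0, nrow = 2 * nGenes, ncol = nS)
    for (j in seq_len(nS)) {
      muEx <- baseline * libFac[j] *
        (if (isCase[j]) 2^exonFac else rep(1, nGenes))
      muIn <- baseline * intronFraction * libFac[j] *
        (if (isCase[j]) 2^intronFac else rep(1, nGenes))
      counts[, j] <- rdraw(c(muEx, muIn))
    }
    colnames(counts) <- sprintf("%s_%02d", group, c(seq_len(nPerGroup),
                                                    seq_len(nPerGroup)))
    # sequencing depth reflects the baseline transcriptome mass, so injected
    # shifts are not diluted by the extra reads they generate
    libSize <- round(sum(baseline * (1 + intronFraction)) * libFac)
    fce <- FeatureCountExperiment(
      counts,
      geneId = c(geneIds, geneIds),
      featureType = rep(c("exon", "intron"), each = nGenes),
      lengthBp = c(exonLen, intronLen),
      group = group,
      librarySize = libSize)
    sheet <- data.frame(sample_id = colnames(counts), group = group,
                        library_size = libSize)
    truth <- data.frame(gene_id = geneIds,
                        baseline_mean = baseline,
                        intron_log2_factor = intronFac,
                        exon_log2_factor = exonFac,
                        in_set = seq_len(nGenes) %in% setIdx)
    list(experiment = fce, sampleSheet = sheet,
         geneSet = GeneSet("simulated_set", geneIds[setIdx],
                           source = "simulateCounts"),
         truth = truth, config = config)
  })
}

#' Simulate a qPCR plate from known fold changes
#'
#' Ct values are `baselineCt(target) - log2(true fold) + Normal(0, sd)` per
#' technical well; the reference target's Ct is constant across conditions up
#' to the same noise.  With `ctNoiseSd = 0`, [relativeExpression()] recovers
#' the generating fold changes exactly.
#'
#' @param seed integer seed.
#' @param trueFold numeric matrix of true fold changes, rows = conditions,
#'   columns = targets.  A row for `controlCondition` (all 1) is added if
#'   absent.
#' @param controlCondition,referenceTarget plate metadata (see
#'   [QpcrPlate-class]).
#' @param nBio,nTech biological and technical replicates per condition.
#' @param ctNoiseSd Gaussian Ct noise (cycles) per technical well.
#' @param baselineCt target baseline Ct (scalar or named per-target vector).
#' @param referenceCt Ct of the reference target.
#' @return list with `plate` (a [QpcrPlate-class]) and `truth` (long data
#'   frame of condition, target, fold).
#' @export
simulateQpcr <- function(seed = 1, trueFold,
                         controlCondition = "control",
                         referenceTarget = "GAPDH", nBio = 3, nTech = 2,
                         ctNoiseSd = 0.2, baselineCt = 25, referenceCt = 18) {
  trueFold <- as.matrix(trueFold)
  .stopIfNot(!is.null(rownames(trueFold)) && !is.null(colnames(trueFold)),
             "trueFold needs condition rownames and target colnames")
  if (!controlCondition %in% rownames(trueFold)) {
    trueFold <- rbind(trueFold,
                      matrix(1, 1, ncol(trueFold),
                             dimnames = list(controlCondition, NULL)))
  }
  .stopIfNot(all(trueFold > 0), "fold changes must be positive")
  targets <- colnames(trueFold)
  base <- if (length(baselineCt) == 1L)
    stats::setNames(rep(baselineCt, length(targets)), targets)
  else baselineCt[targets]
  withr::with_seed(seed, {
    rows <- list()
    for (cond in rownames(trueFold)) {
      for (b in seq_len(nBio)) {
        sid <- sprintf("%s_rep%d", cond, b)
        for (tg in c(targets, referenceTarget)) {
          mu <- if (tg == referenceTarget) referenceCt
                else base[tg] - log2(trueFold[cond, tg])
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, condition = cond, target = tg,
            replicate = seq_len(nTech),
            ct = mu + stats::rnorm(nTech, 0, ctNoiseSd))
        }
      }
    }
    wells <- do.call(rbind, rows)
    truth <- data.frame(
      condition = rep(rownames(trueFold), times = length(targets)),
      target = rep(targets, each = nrow(trueFold)),
      fold = as.vector(trueFold))
    list(plate = QpcrPlate(wells, referenceTarget = referenceTarget,
                           controlCondition = controlCondition),
         truth = truth)
  })
}

# Hill-shaped dose -> repression map (log2 units); only monotonicity matters
# to the fitted repression -> abundance model
.hillRepression <- function(conc, rmax, ec50, hill) {
  rmax * conc^hill / (conc^hill + ec50^hill)
}

#' Simulate a dose-response experiment under the zero-intercept model
#'
#' Doses map to true translational repression through a monotone Hill curve
#' per compound (over the working ranges of PR20, 0.5-8 uM, and CHX,
#' 0.0075-0.24 ug/mL); each target's log2 fold change is `beta * repression +
#' Normal(0, noiseSd)`.  Luciferase activity and mRNA readings carry their own
#' small log-normal measurement noise.  With all noise at 0,
#' [doseResponsePipeline()] returns `100 * betaPr / betaChx` exactly.
#'
#' @param seed integer seed.
#' @param betaPr,betaChx true slopes (recycled over targets).
#' @param targets target transcript names.
#' @param noiseSd log2-scale noise sd on target abundances (default 0.1).
#' @param lucNoiseSd log2-scale measurement noise on luciferase activity and
#'   mRNA readings (default 0.05).
#' @param nReplicates replicates per concentration (default 3).
#' @param prConc,chxConc concentration grids (4 doses each by default).
#' @param prHill,chxHill Hill parameters `c(rmax, ec50, hill)` of the
#'   dose-to-repression maps.
#' @return list with `points` (dose-response table as read by
#'   [readDoseResponse()]) and `truth` (per-target slopes and the true
#'   fraction explained, percent).
#' @export
simulateDoseResponse <- function(seed = 1, betaPr = 1, betaChx = 1,
                                 targets = c("nmd_target_1", "nmd_target_2",
                                             "nmd_target_3"),
                                 noiseSd = 0.1, lucNoiseSd = 0.05,
                                 nReplicates = 3,
                                 prConc = c(1, 2, 4, 8),
                                 chxConc = c(0.03, 0.06, 0.12, 0.24),
                                 prHill = c(3, 2, 1.5),
                                 chxHill = c(3.5, 0.06, 1.2)) {
  betaPr <- rep_len(betaPr, length(targets))
  betaChx <- rep_len(betaChx, length(targets))
  names(betaPr) <- names(betaChx) <- targets
  grid <- rbind(
    data.frame(compound = "DMSO", concentration = 0, conc_units = "pct",
               repression_true = 0),
    data.frame(compound = "PR20", concentration = prConc, conc_units = "uM",
               repression_true = .hillRepression(prConc, prHill[1], prHill[2],
                                                 prHill[3])),
    data.frame(compound = "CHX", concentration = chxConc,
               conc_units = "ug/mL",
               repression_true = .hillRepression(chxConc, chxHill[1],
                                                 chxHill[2], chxHill[3])))
  withr::with_seed(seed, {
    pts <- grid[rep(seq_len(nrow(grid)), each = nReplicates), ]
    pts$replicate <- rep(seq_len(nReplicates), times = nrow(grid))
    n <- nrow(pts)
    pts$luc_mrna <- 100 * 2^stats::rnorm(n, 0, lucNoiseSd)
    pts$luc_activity <- 1000 * 2^(-pts$repression_true) *
      (pts$luc_mrna / 100) * 2^stats::rnorm(n, 0, lucNoiseSd)
    rows <- lapply(targets, function(tg) {
      beta <- ifelse(pts$compound == "PR20", betaPr[tg],
                     ifelse(pts$compound == "CHX", betaChx[tg], 0))
      ab <- 2^(beta * pts$repression_true + stats::rnorm(n, 0, noiseSd))
      cbind(pts[c("compound", "concentration", "conc_units", "replicate",
                  "luc_activity", "luc_mrna")],
            data.frame(target = tg, target_abundance = ab))
    })
    points <- do.call(rbind, rows)
    rownames(points) <- NULL
    truth <- data.frame(target = targets, beta_pr = unname(betaPr),
                        beta_chx = unname(betaChx),
                        fraction_pct = 100 * unname(betaPr) / unname(betaChx))
    list(points = points, truth = truth)
  })
}

#' Simulate paired neuronal survival counts
#'
#' Per independent experiment and condition, the number of neurons counted
#' before treatment is Poisson around `nT0Mean` (at least 1) and the number
#' surviving 48 h is Binomial with the condition's true survival probability.
#'
#' @param seed integer seed.
#' @param probs named vector of true survival probabilities per condition
#'   (first element is conventionally the vector-only control).
#' @param nExperiments independent experiments (pairing unit).
#' @param nT0Mean mean neurons counted at t0 per experiment.
#' @return list with `records` (condition, experiment_id, n_t0, n_t48) and
#'   `truth`.
#' @export
simulateSurvival <- function(seed = 1,
                             probs = c(vector = 0.2, UPF1 = 0.342),
                             nExperiments = 6, nT0Mean = 100) {
  .stopIfNot(!is.null(names(probs)) && all(probs >= 0 & probs <= 1),
             "probs must be a named vector of probabilities")
  withr::with_seed(seed, {
    records <- do.call(rbind, lapply(seq_len(nExperiments), function(e) {
      nT0 <- pmax(1L, stats::rpois(length(probs), nT0Mean))
      data.frame(condition = names(probs), experiment_id = e,
                 n_t0 = nT0,
                 n_t48 = stats::rbinom(length(probs), nT0, probs))
    }))
    rownames(records) <- NULL
    list(records = records,
         truth = data.frame(condition = names(probs),
                            survival_prob = unname(probs)))
  })
}

#' Simulate stress-granule-positive cell counts
#'
#' Binomial SG-positive counts per condition and experiment at the configured
#' true fractions.
#'
#' @param seed integer seed.
#' @param probs named vector of true SG-positive fractions per condition.
#' @param nExperiments independent experiments.
#' @param nTransfected transfected cells scored per experiment.
#' @return list with `records` (condition, experiment_id, n_transfected,
#'   n_sg_positive) and `truth`.
#' @export
simulateSG <- function(seed = 1,
                       probs = c(GFP = 0.02, GR = 0.45, PR = 0.24),
                       nExperiments = 4, nTransfected = 100) {
  .stopIfNot(!is.null(names(probs)) && all(probs >= 0 & probs <= 1),
             "probs must be a named vector of probabilities")
  withr::with_seed(seed, {
    records <- do.call(rbind, lapply(seq_len(nExperiments), function(e) {
      data.frame(condition = names(probs), experiment_id = e,
                 n_transfected = nTransfected,
                 n_sg_positive = stats::rbinom(length(probs), nTransfected,
                                               probs))
    }))
    rownames(records) <- NULL
    list(records = records,
         truth = data.frame(condition = names(probs),
                            sg_prob = unname(probs)))
  })
}
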