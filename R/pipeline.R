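#' Read a run configuration
#'
#' A single YAML document holding input paths, contrast definitions and
#' analysis options.  Recognised top-level keys: `outdir`, `seed`, `pseudo`,
#' `min_mean_reads`, `alternative`, `counts`, `sample_sheet`, `gene_sets`
#' (list of files), `case`, `control`, `qpcr_plate`, `reference_target`,
#' `control_condition`, `dose_response`, `reference_compound`, `survival`,
#' `sg`, `survival_control`, `sg_control`, `simulate` (sub-list of generator
#' overrides).  Unknown keys are kept verbatim so subcommands can consume
#' them.
#'
#' @param path YAML file path.
#' @param overrides named list merged over the file contents (command-line
#'   flags win over the file).
#' @return the configuration as a named list with defaults filled in.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  config <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) config[[nm]] <- overrides[[nm]]
  defaults <- list(outdir = "nmdshift_out", seed = 1L, pseudo = 0.1,
                   min_mean_reads = 1.0, alternative = "two.sided",
                   reference_target = "GAPDH",
                   reference_compound = "CHX")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("counts", "sample_sheet", "qpcr_plate", "dose_response",
               "survival", "sg"))
    if (!is.null(config[[nm]]))
      .stopIfNot(file.exists(config[[nm]]),
                 "configured path does not exist: ", config[[nm]])
  for (gs in config$gene_sets)
    .stopIfNot(file.exists(gs), "configured path does not exist: ", gs)
  config
}

.writeManifest <- function(outdir, subcommand, config, inputs, artifacts) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    subcommand = subcommand,
    package = "nmdshift",
    version = as.character(utils::packageVersion("nmdshift")),
    parameters = config[!vapply(config, is.list, logical(1))],
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    artifacts = basename(unlist(artifacts)))
  path <- file.path(outdir, paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

.loadExperiment <- function(config) {
  .stopIfNot(!is.null(config$counts), "config key 'counts' is required")
  sheet <- if (!is.null(config$sample_sheet))
    readSampleSheet(config$sample_sheet) else NULL
  fce <- readCountTable(config$counts, sheet)
  if (!is.null(config$case)) {
    groups <- unique(sampleGroups(fce))
    for (g in c(config$case, config$control))
      .stopIfNot(g %in% groups, "contrast group '", g,
                 "' not present in the sample sheet")
  }
  filterLowExpression(fce, config$min_mean_reads)
}

.runSimulate <- function(config, outdir) {
  sim <- config$simulate
  arg <- function(nm, default) if (is.null(sim[[nm]])) default else sim[[nm]]
  seed <- config$seed
  cs <- do.call(simulateCounts, c(list(seed = seed),
                                  sim[intersect(names(sim),
                                                names(formals(simulateCounts)))]))
  paths <- c(
    counts = writeCountTable(cs$experiment, file.path(outdir, "sim_counts.tsv")),
    sheet = writeSampleSheet(cs$sampleSheet,
                             file.path(outdir, "sim_sample_sheet.csv")),
    truth = .writeTsv(cs$truth, file.path(outdir, "sim_counts_truth.tsv")))
  writeLines(cs$geneSet@members, file.path(outdir, "sim_gene_set.txt"))
  paths["gene_set"] <- file.path(outdir, "sim_gene_set.txt")

  qp <- simulateQpcr(seed = seed + 1,
                     trueFold = arg("true_fold",
                                    matrix(c(2, 3), 1, 2,
                                           dimnames = list("treated",
                                                           c("target_a",
                                                             "target_b")))),
                     controlCondition = arg("control_condition", "control"),
                     ctNoiseSd = arg("ct_noise_sd", 0.2))
  utils::write.csv(wells(qp$plate), file.path(outdir, "sim_qpcr_plate.csv"),
                   row.names = FALSE, quote = FALSE)
  paths["qpcr"] <- file.path(outdir, "sim_qpcr_plate.csv")
  paths["qpcr_truth"] <- .writeTsv(qp$truth,
                                   file.path(outdir, "sim_qpcr_truth.tsv"))

  dr <- simulateDoseResponse(seed = seed + 2,
                             betaPr = arg("beta_pr", 1),
                             betaChx = arg("beta_chx", 1),
                             noiseSd = arg("dose_noise_sd", 0.1))
  utils::write.csv(dr$points, file.path(outdir, "sim_dose_response.csv"),
                   row.names = FALSE, quote = FALSE)
  paths["dose"] <- file.path(outdir, "sim_dose_response.csv")
  paths["dose_truth"] <- .writeTsv(dr$truth,
                                   file.path(outdir, "sim_dose_truth.tsv"))

  sv <- simulateSurvival(seed = seed + 3)
  sg <- simulateSG(seed = seed + 4)
  utils::write.csv(sv$records, file.path(outdir, "sim_survival.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sg$records, file.path(outdir, "sim_sg.csv"),
                   row.names = FALSE, quote = FALSE)
  paths["survival"] <- file.path(outdir, "sim_survival.csv")
  paths["sg"] <- file.path(outdir, "sim_sg.csv")
  paths["phenotype_truth"] <- .writeTsv(rbind(
    data.frame(kind = "survival", condition = sv$truth$condition,
               prob = sv$truth$survival_prob),
    data.frame(kind = "sg", condition = sg$truth$condition,
               prob = sg$truth$sg_prob)),
    file.path(outdir, "sim_phenotype_truth.tsv"))
  paths
}

.runQuant <- function(config, outdir) {
  fce <- computeDensity(.loadExperiment(config))
  long <- data.frame(gene_id = geneId(fce), feature_type = featureType(fce),
                     length_bp = featureLength(fce))
  for (a in c("counts", "rpm", "density_per_kb")) {
    m <- assay(fce, a)
    colnames(m) <- paste(a, colnames(m), sep = ".")
    long <- cbind(long, as.data.frame(m))
  }
  long <- long[order(long$gene_id, long$feature_type), ]
  c(density = .writeTsv(long, file.path(outdir, "density.tsv")))
}

.runRetention <- function(config, outdir) {
  .stopIfNot(!is.null(config$case) && !is.null(config$control),
             "retention needs 'case' and 'control' groups in the config")
  fce <- computeDensity(.loadExperiment(config))
  fcIn <- foldChange(fce, config$case, config$control,
                     pseudo = config$pseudo, feature = "intron")
  fcEx <- foldChange(fce, config$case, config$control,
                     pseudo = config$pseudo, feature = "exon")
  alt <- config$retention_alternative
  if (is.null(alt)) alt <- "greater"
  summ <- intronRetentionSummary(fcIn, fcEx, alternative = alt)
  res <- summ$result
  out <- data.frame(case = config$case, control = config$control,
                    n_introns = res@nSet, n_reference = res@nBackground,
                    median_log2fc = summ$medianLog2fc,
                    median_fold_change = summ$medianFoldChange,
                    U = res@U, p_value = res@pValue,
                    alternative = res@alternative)
  c(summary = .writeTsv(out, file.path(outdir, "retention_summary.tsv")),
    hist = .writeTsv(summ$histogram, file.path(outdir, "retention_hist.tsv")),
    fc = .writeTsv(as.data.frame(fcIn), file.path(outdir, "intron_fc.tsv")))
}

.runSetshift <- function(config, outdir) {
  .stopIfNot(length(config$gene_sets) >= 1L,
             "setshift needs at least one gene_sets file")
  fce <- computeDensity(.loadExperiment(config))
  fc <- foldChange(fce, config$case, config$control, pseudo = config$pseudo,
                   feature = "gene")
  paths <- character()
  rows <- lapply(config$gene_sets, function(gsPath) {
    gs <- readGeneSet(gsPath)
    res <- genesetShiftTest(fc, gs, alternative = config$alternative)
    ep <- .writeTsv(cbind(data.frame(which = c(rep("set", nrow(res@ecdfSet)),
                                               rep("background",
                                                   nrow(res@ecdfBackground)))),
                          rbind(res@ecdfSet, res@ecdfBackground)),
                    file.path(outdir, paste0("ecdf_", gs@name, ".tsv")))
    paths[[paste0("ecdf_", gs@name)]] <<- ep
    data.frame(set = gs@name, n_set = res@nSet, n_requested = res@nRequested,
               n_background = res@nBackground,
               median_set = res@medianSet,
               median_background = res@medianBackground,
               median_shift = res@medianShift, U = res@U,
               p_value = res@pValue, alternative = res@alternative)
  })
  c(setshift = .writeTsv(do.call(rbind, rows),
                         file.path(outdir, "setshift_results.tsv")),
    paths)
}

.runQpcr <- function(config, outdir) {
  .stopIfNot(!is.null(config$qpcr_plate) && !is.null(config$control_condition),
             "qpcr needs 'qpcr_plate' and 'control_condition' in the config")
  plate <- readQpcrPlate(config$qpcr_plate,
                         referenceTarget = config$reference_target,
                         controlCondition = config$control_condition)
  res <- relativeExpression(plate)
  c(qpcr = .writeTsv(res, file.path(outdir, "qpcr_results.tsv")),
    reps = .writeTsv(attr(res, "replicates"),
                     file.path(outdir, "qpcr_replicates.tsv")))
}

.runDose <- function(config, outdir) {
  .stopIfNot(!is.null(config$dose_response),
             "dose needs 'dose_response' in the config")
  df <- readDoseResponse(config$dose_response)
  res <- doseResponsePipeline(df, referenceCompound = config$reference_compound,
                              nBoot = 0)
  c(fits = .writeTsv(res$fits, file.path(outdir, "dose_fits.tsv")),
    fractions = .writeTsv(res$fractions,
                          file.path(outdir, "dose_fractions.tsv")),
    plot = .writeTsv(res$plotData, file.path(outdir, "dose_plotdata.tsv")))
}

.runPhenotype <- function(config, outdir) {
  paths <- character()
  if (!is.null(config$survival)) {
    sv <- utils::read.csv(config$survival, stringsAsFactors = FALSE)
    ctrl <- if (!is.null(config$survival_control)) config$survival_control
            else sv$condition[1]
    paths["survival"] <- .writeTsv(relativeSurvival(sv, ctrl),
                                   file.path(outdir, "survival_results.tsv"))
  }
  if (!is.null(config$sg)) {
    sg <- utils::read.csv(config$sg, stringsAsFactors = FALSE)
    ctrl <- if (!is.null(config$sg_control)) config$sg_control
            else sg$condition[1]
    paths["sg"] <- .writeTsv(sgPositiveStats(sg, ctrl),
                             file.path(outdir, "sg_results.tsv"))
  }
  .stopIfNot(length(paths) > 0,
             "phenotype needs 'survival' and/or 'sg' in the config")
  paths
}

.runReport <- function(config, outdir) {
  stage <- function(file) {
    p <- file.path(outdir, file)
    if (file.exists(p)) .readTsv(p) else NULL
  }
  fmtTable <- function(df) {
    if (is.null(df)) return("(stage not run)")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 4))
    paste(c(paste(colnames(df), collapse = "\t"),
            apply(df, 1L, paste, collapse = "\t")), collapse = "\n")
  }
  sections <- c(
    "# nmdshift run summary", "",
    "## Intron retention", fmtTable(stage("retention_summary.tsv")), "",
    "## Gene-set shifts", fmtTable(stage("setshift_results.tsv")), "",
    "## qPCR relative expression", fmtTable(stage("qpcr_results.tsv")), "",
    "## Dose-response fraction explained", fmtTable(stage("dose_fractions.tsv")), "",
    "## Neuronal survival", fmtTable(stage("survival_results.tsv")), "",
    "## Stress-granule fractions", fmtTable(stage("sg_results.tsv")), "")
  path <- file.path(outdir, "report.md")
  writeLines(sections, path)
  c(report = path)
}

#' Run one pipeline stage
#'
#' Dispatches to one of the stage runners, writing deterministic TSV/CSV
#' artifacts plus a JSON manifest (parameters, input MD5 hashes, package
#' version) into the configured output directory.  On failure, files written
#' by the failing stage are removed.
#'
#' @param name one of `"simulate"`, `"quant"`, `"retention"`, `"setshift"`,
#'   `"qpcr"`, `"dose"`, `"phenotype"`, `"report"`.
#' @param config configuration list (see [readRunConfig()]).
#' @return invisibly, a named character vector of artifact paths.
#' @export
runSubcommand <- function(name, config = list()) {
  known <- c("simulate", "quant", "retention", "setshift", "qpcr", "dose",
             "phenotype", "report")
  if (length(name) != 1L || !name %in% known)
    stop("unknown subcommand '", paste(name, collapse = ","),
         "'; usage: runSubcommand(<", paste(known, collapse = "|"),
         ">, config)")
  config <- readRunConfig(NULL, overrides = config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  runner <- switch(name, simulate = .runSimulate, quant = .runQuant,
                   retention = .runRetention, setshift = .runSetshift,
                   qpcr = .runQpcr, dose = .runDose,
                   phenotype = .runPhenotype, report = .runReport)
  preexisting <- list.files(outdir, full.names = TRUE)
  artifacts <- tryCatch(
    runner(config, outdir),
    error = function(e) {
      # remove partial outputs of this stage before propagating
      added <- setdiff(list.files(outdir, full.names = TRUE), preexisting)
      unlink(added)
      stop("subcommand '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  inputs <- config[c("counts", "sample_sheet", "qpcr_plate", "dose_response",
                     "survival", "sg")]
  if (length(config$gene_sets))
    inputs <- c(inputs,
                stats::setNames(as.list(config$gene_sets),
                                paste0("gene_set_",
                                       seq_along(config$gene_sets))))
  message("nmdshift ", name, ": wrote ", length(artifacts), " artifact(s) to ",
          outdir)
  .writeManifest(outdir, name, config, inputs, artifacts)
  invisible(unlist(artifacts))
}
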