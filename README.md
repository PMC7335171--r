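# nmdshift

Quantifying inhibition of UPF1-mediated RNA decay — including
nonsense-mediated decay (NMD) — from bulk expression data, RT-qPCR,
dose-response experiments and neuronal phenotype counts.

## The problem

When RNA surveillance fails (as in C9orf72 ALS/FTD, where arginine-rich
dipeptide repeat proteins repress translation and thereby the
translation-dependent NMD pathway), no single gene tells the story. The
signature is distributional: intronic read densities rise relative to exonic
signal, published NMD-target gene sets shift upward as a whole, individual
targets accumulate in qPCR, and the accumulation scales with measured
translational repression. `nmdshift` implements these quantifications for
analysts who have count tables, plates, and count sheets in hand — alignment,
image segmentation and gene-set construction are upstream and out of scope.

## What it computes

* **Read densities and fold changes** — per-gene exon/intron counts in a
  `FeatureCountExperiment` (a `SummarizedExperiment`); exclusion of genes
  with a mean of < 1 read/sample; RPM and per-kb densities; pseudo-count
  stabilised group fold changes,
  `log2((mean_case + 0.1) / (mean_control + 0.1))`. Desk-scale BED interval
  counting with exon priority for junction reads is included
  (`countFeatureReads`), pinned to a brute-force oracle in the tests.
* **Distribution shifts** — Mann–Whitney U with midranks, exact small-sample
  tails and tie/continuity-corrected normal approximation (`mannWhitney`);
  intron-retention summaries with histogram export
  (`intronRetentionSummary`); gene-set ECDF shift tests
  (`genesetShiftTest`); control-normalised per-gene group comparisons
  (`perGeneGroupCompare`).
* **qPCR** — technical-replicate averaging with spread QC, comparative-Ct
  (ΔΔCt) relative expression with geometric-mean summaries, one-sample ratio
  t-tests on log2 fold changes, and nuclear-fraction estimation
  `A_nuc / (A_nuc + A_cyt)` from fractionated plates.
* **Dose-response decomposition** — translational activity from a luciferase
  reporter (activity = luc activity / luc mRNA, vehicle-normalised),
  zero-intercept log–log fits `beta = sum(xy)/sum(x^2)` of target
  accumulation against repression `-log2(activity)`, and the
  fraction-explained statistic `F = 100 * beta_test / beta_CHX` (%), with
  cycloheximide as the pure-translation-inhibition reference.
* **Phenotypes** — survival fractions, paired relative-survival percent
  changes with log-ratio t-tests, stress-granule-positive fractions with
  unpaired t-tests.
* **Synthetic data** — seeded generators (`simulateCounts`, `simulateQpcr`,
  `simulateDoseResponse`, `simulateSurvival`, `simulateSG`) that return the
  ground truth they injected, so every analysis stage is validated by
  parameter recovery.
* **Pipeline** — `runSubcommand()` over a YAML config (stages: simulate,
  quant, retention, setshift, qpcr, dose, phenotype, report), deterministic
  TSV artifacts, JSON run manifests, and a CLI wrapper in
  `inst/scripts/nmdshift-cli.R`.

## Worked example

```r
library(nmdshift)

## two-group counts with a known median 2.1x intron shift and a shifted set
sim <- simulateCounts(seed = 1, nGenes = 2000, nSet = 150, nPerGroup = 6)
fce <- computeDensity(filterLowExpression(sim$experiment))

fcIntron <- foldChange(fce, "case", "control", feature = "intron")
fcExon   <- foldChange(fce, "case", "control", feature = "exon")
ret <- intronRetentionSummary(fcIntron, fcExon, alternative = "greater")
ret$result
#> ShiftTestResult 'introns': n = 2000 vs 2000 background
#>   median 1.048 vs 0.02605 (shift +1.022)
#>   Mann-Whitney U = 3.89831e+06, greater p = 2.225e-308
ret$medianFoldChange
#> [1] 2.07
```

The median intron read-density fold change recovered from the simulated data
(2.07) sits just under the injected median of 2.1 — the 0.1 pseudo-RPM
shrinks low-abundance genes toward 1 — and the one-sided Mann–Whitney test
against the exonic fold changes is overwhelming, as it should be for a
global retention shift.

```r
fcGene <- foldChange(fce, "case", "control", feature = "gene")
genesetShiftTest(fcGene, sim$geneSet)
#> ShiftTestResult 'simulated_set': n = 150 vs 1850 background
#>   median 0.5113 vs 0.004221 (shift +0.5071)
#>   Mann-Whitney U = 240874, two.sided p = 6.055e-51
```

The 150-gene set injected with a +0.5 log2 shift is recovered with a median
shift of +0.51 against an essentially unshifted background.

```r
qp <- simulateQpcr(seed = 2,
                   trueFold = matrix(c(2.5, 1.8), 1, 2,
                                     dimnames = list("PR", c("ATF4", "GAS5"))),
                   controlCondition = "GFP")
relativeExpression(qp$plate)
#>   condition target n mean_log2fc sd_log2fc fold_change p_value
#> 1       GFP   ATF4 3       0.000     0.311        1.00 1.00000
#> 2       GFP   GAS5 3       0.000     0.247        1.00 1.00000
#> 3        PR   ATF4 3       1.350     0.087        2.55 0.00138
#> 4        PR   GAS5 3       0.811     0.108        1.75 0.00585
```

ΔΔCt recovers the generating fold changes (2.5 and 1.8) within the 0.2-cycle
Ct noise; the control condition is exactly 1 by construction and the ratio
t-tests flag both targets.

```r
dose <- simulateDoseResponse(seed = 3, betaPr = 1, betaChx = 1)
fit <- doseResponsePipeline(dose$points)
fit$fractions[c("target", "fraction_pct", "slope_pr", "slope_chx")]
#>         target fraction_pct slope_pr slope_chx
#> 1 nmd_target_1        101.1    1.065     1.053
#> 2 nmd_target_2         99.5    0.973     0.978
#> 3 nmd_target_3        101.2    1.016     1.004
```

With equal true slopes, the fraction of NMD-target accumulation explained by
translational repression is recovered at ~100% for every target: the
compound's effect on the targets is fully accounted for by its effect on
translation.

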