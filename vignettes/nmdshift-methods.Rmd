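---
title: "Methods: quantifying inhibition of UPF1-mediated RNA decay"
author: "nmdshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying inhibition of UPF1-mediated RNA decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdshift)
```

## Scientific background

Nonsense-mediated decay (NMD) and related UPF1-dependent pathways degrade
misprocessed mRNAs (for example intron-retaining transcripts with premature
stop codons) and tune the abundance of many regulatory targets.  When these
pathways are inhibited — as happens in C9orf72 ALS/FTD, where arginine-rich
dipeptide repeat proteins repress translation, on which NMD depends — a
characteristic, multi-assay signature emerges:

* intronic read densities rise relative to exonic signal in RNA-seq;
* published NMD-target gene sets (and UPF1-dependent canonical histone
  mRNAs) shift upward as a distribution, even when individual genes are not
  significant;
* individual targets accumulate in qPCR, in the cytoplasm rather than the
  nucleus;
* the accumulation scales with the degree of translational repression, which
  can be measured directly with a luciferase reporter.

`nmdshift` implements each of these quantifications as a small, testable
operation, plus seeded generators that simulate data with known ground truth
so every stage can be validated end to end by parameter recovery.

## Read densities and fold changes

Counts are held per (gene, feature type) row — `exon` and `intron` rows per
gene — in a `FeatureCountExperiment` (a `SummarizedExperiment`).  Genes with
a mean of fewer than 1 read per sample (summed over the gene's feature rows)
are excluded; a gene at exactly the threshold is retained, and the filter is
idempotent.  Densities are reads per million uniquely mapped reads (RPM), and
per-kilobase density divides the RPM by the merged feature length.  When
library sizes are not supplied, the per-sample total of assigned reads is
used instead, with a warning, since assigned reads underestimate the uniquely
mapped total.

Fold changes are computed on group means with a pseudo-count:

\[
\log_2\mathrm{FC} = \log_2\frac{\bar v_{\mathrm{case}} + 0.1}
                               {\bar v_{\mathrm{control}} + 0.1}
\]

`feature = "gene"` contrasts gene RPM from the exonic rows (mRNA abundance);
`feature = "intron"` and `"exon"` contrast per-kilobase densities.  The 0.1
pseudo-count, applied to all values, keeps every fold change finite and
shrinks low-abundance features toward a fold change of 1; it is configurable.
"Intron read density" is operationalised as RPM per kilobase of merged
intronic length aggregated per gene; a per-interval analysis is possible by
supplying intervals as separate rows.

For interval-level counting (`countFeatureReads`), coordinates follow the BED
convention (0-based, half-open on disk; imported to the 1-based closed
`GRanges` convention, which preserves overlap semantics).  A read is assigned
per gene with exon priority: any 1-bp overlap with an exon makes the read
exonic for that gene; otherwise an intron overlap makes it intronic.  This
prevents junction-spanning reads from being counted twice.  Strand is
ignored, since the counting rule is not specified strand-aware anywhere we
rely on; the brute-force all-pairs oracle in the test suite pins the exact
semantics.

## Distribution-shift statistics

Intron-retention and gene-set analyses are rank-based.  The Mann-Whitney U
statistic is computed with midranks; the p-value uses the exact null tail
(via the null U distribution) whenever there are no ties and
\(n_x n_y \le 400\), and otherwise a normal approximation with tie correction
and continuity correction.  The test suite checks the exact branch against
brute-force enumeration of all labelings for every design up to 7 vs 7, and
the approximate branch against the reference implementation in `stats`.

The intron-retention summary tests the intron fold-change distribution
against a reference distribution, one-sided (`greater`) by default.  The
reference is deliberately an argument: the natural in-sample choice is the
same contrast's exonic fold changes (so a global expression shift cancels),
but a second contrast's intron fold changes can be supplied instead.  Both
readings are legitimate; neither is asserted as canonical.

Gene-set shift tests compare set members against the complement of the set by
default — using all genes as "background" double-counts the members, which is
conservative for large sets; `background = "all"` restores the inclusive
convention for comparison with published CDF figures.  No multiple-testing
correction is applied by default because each figure-style analysis reports
raw p-values across a handful of sets; `p.adjust` can be applied downstream.

Per-gene group comparisons normalise each gene by its control-group mean
(control mean of exactly 1 by construction) and use the classical
pooled-variance two-sided t-test by default, with Welch's form behind a flag;
"unpaired t test" without qualification conventionally means the pooled form
at these sample sizes.  When both groups have zero spread the limiting values
are reported (t = 0, p = 1 for equal means; p = 0 otherwise).  Box statistics
use quartiles with whiskers at the most extreme points within 1.5 IQR.

## qPCR relative quantification

Technical replicates are averaged first (a spread above 0.5 cycles within a
well group is flagged — clean technical duplicates rarely differ by more);
biological replicates are samples.  Relative expression follows the standard
comparative-Ct scheme at 100% amplification efficiency:
\(\Delta Ct = Ct_{\mathrm{target}} - Ct_{\mathrm{GAPDH}}\),
\(\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{\mathrm{control}}\),
fold change \(= 2^{-\Delta\Delta Ct}\).  A per-target efficiency override is
available.  Summary fold changes are geometric means of per-replicate fold
changes, making the control condition exactly 1.

The "ratio t-test" is operationalised as the standard reading: a two-sided
one-sample t-test of per-replicate log2 fold changes against 0 (ratio = 1).
Testing on the log scale is assumed rather than on raw ratios, since ratios
are multiplicative and only log ratios are symmetric about the null.

Nuclear fractions convert each fraction's Ct to a relative abundance
\(2^{-Ct}\) and report \(A_{nuc}/(A_{nuc}+A_{cyt})\), assuming equal fraction
volumes and applying no cross-fraction normaliser: compartment-restricted
species (U1 snRNA nuclear, GAPDH mRNA cytoplasmic) serve as internal
controls for the fractionation itself.  The fraction is always in [0, 1] and
monotone decreasing in the nuclear Ct.

## Dose-response decomposition

The core quantity asks how much of a compound's effect on NMD targets is
accounted for by its effect on translation.  Translational activity is the
luciferase activity / luciferase mRNA ratio normalised to the vehicle-control
mean; repression is \(-\log_2(\mathrm{activity})\), so inhibitors give
positive repression.  Concentration enters only through the measured
repression — the model relates target accumulation to repression, not to
dose, so the dose-to-repression map may be arbitrary.

For each compound and target, a least-squares line through the origin is fit
to (repression, log2 target fold change) points:
\(\hat\beta = \sum x_i y_i / \sum x_i^2\), with
\(se(\hat\beta) = \sqrt{RSS/(n-1)/\sum x_i^2}\).  The zero intercept encodes
the null state: zero repression means zero accumulation, and vehicle-control
points (which define the fold-change origin as the geometric mean of control
abundances) are excluded from the fits.  The fraction of NMD-target
accumulation explained by translational repression is the slope ratio

\[
F = 100 \times \beta_{\mathrm{test}} / \beta_{\mathrm{CHX}} \ (\%),
\]

with cycloheximide — a pure translation-elongation inhibitor — as the
reference for how much accumulation a unit of repression produces when
translation inhibition is the only mechanism.  The slope-ratio
operationalisation is this package's interpretation: it is the reading that
yields a per-target percentage from two zero-intercept log-log fits, and F is
invariant to rescaling both repression axes by a common factor.  Pooled-point
fitting is the default; a per-replicate mode (fit each replicate series, then
average slopes) is available, as is a seeded percentile bootstrap (2000
resamples of points within each fit) for a confidence interval.

## Phenotype statistics

Neuronal survival is the fraction of labelled neurons present at 48 h,
\(S = n_{48}/n_0\).  Relative survival pairs each condition with the control
within independent experiments (the pairing unit), reports the mean of
per-experiment ratios as a percent change — the "average increase"
aggregation; the ratio of means is reported alongside — and tests the log
ratios with a two-sided paired t-test.  Stress-granule-positive fractions are
per-experiment proportions compared by unpaired t-tests on the untransformed
fractions (appropriate at n of 3-4 experiments; an arcsine-square-root option
is provided).

## Synthetic data generators

Each generator is a pure function of its arguments and an integer seed (the
global RNG state is saved and restored), and returns the ground truth it
injected, so recovery tests are exact.

* **Counts** (`simulateCounts`): per-gene baseline expression is log-normal
  (median 200 expected exonic reads, log-sd 1 — a realistic bulk dynamic
  range); counts are negative-binomial with dispersion 0.1, the typical
  over-dispersion of bulk RNA-seq; baseline intronic signal is 15% of the
  gene's exonic level; 8 samples per group.  The case group's intron
  expectations are inflated by gene-specific log-normal factors with median
  \(2^{\log_2 2.1} = 2.1\) (log2-sd 0.25), matching the magnitude of the
  intron-retention shift the pipeline is designed to detect; set-member exon
  expectations are shifted by Normal(0.5, 0.25) log2 units.  Library sizes
  are set to each sample's expected baseline read total (depth factor times
  the unshifted transcriptome mass): sequencing depth is a property of the
  experiment, and defining it this way expresses the injected factors
  directly in measured-density space instead of diluting them by the extra
  read mass they create.  Real libraries can carry that compositional bias —
  together with pseudo-count shrinkage it is why recovered medians sit a few
  percent below the injected factor — so passing recovery tests demonstrate
  correctness of the computation, not immunity to composition effects.
* **qPCR** (`simulateQpcr`): Ct = target baseline − log2(true fold) +
  Gaussian noise (sd 0.2 cycles by default, typical of clean SYBR assays),
  two technical replicates, three biological replicates, constant reference
  target.
* **Dose-response** (`simulateDoseResponse`): a monotone Hill map takes the
  working concentration ranges (PR20 at 1-8 µM; CHX at 0.03-0.24 µg/mL, four
  doses each, three replicates) to true repression of up to ~3 log2 units;
  target log2 fold changes follow the zero-intercept model with slope β and
  log2 noise sd 0.1; luciferase readings carry small (0.05 log2 sd)
  measurement noise.  Only monotonicity of the dose map matters to the
  fitted repression-abundance relation.
* **Phenotype** (`simulateSurvival`, `simulateSG`): binomial counts at
  configured per-condition probabilities (defaults 0.2 vs 0.342 survival —
  a +71% relative increase — and 2/45/24% SG-positive fractions), with
  ~100 cells scored per experiment.

What the generators do **not** emulate: spliced-alignment artefacts, gene
length biases shared between exon and intron rows, correlated
between-sample structure (batch), qPCR efficiency drift, or saturating
dose-response curvature.  Passing recovery tests therefore validate the
statistical machinery, not robustness to those real-data complications.

## Numerical choices and problem sizes

* Exact Mann-Whitney switches to the corrected normal approximation at
  \(n_x n_y > 400\) or in the presence of ties.
* The fraction-explained reference slope must exceed 1e-9 in magnitude.
* Fold changes are finite by construction (pseudo-count > 0 enforced).
* Validation simulations use the design sizes the tests state: 5000 genes and
  8 samples per group for retention recovery; 275-member sets against 10 000
  background genes, 2000 null and 200 shifted replicates, for calibration and
  power; 500 replicates of the 4-dose × 3-replicate design for
  fraction-explained recovery.  These sizes give Monte-Carlo standard errors
  comfortably below the tolerances being checked.

## The pipeline layer

`runSubcommand()` exposes the stages (`simulate`, `quant`, `retention`,
`setshift`, `qpcr`, `dose`, `phenotype`, `report`) over a YAML configuration
with flag overrides (flags win); a thin command-line wrapper is installed at
`inst/scripts/nmdshift-cli.R`.  Every stage writes deterministic TSV/CSV
artifacts plus a JSON manifest of parameters, input MD5 hashes and the
package version — enough to re-execute the run — and removes its partial
outputs on failure.  `report` aggregates whatever stage tables exist into a
single summary document.

## Known limitations

* Interval counting is strand-blind and read-level (no fragment model or
  multi-mapping awareness); it is intended for desk-scale validation, not as
  a replacement for a production feature counter.
* The expression filter and fold changes operate on group means; no
  dispersion modelling or shrinkage is attempted, by design — the analyses
  here are distribution-level, not per-gene differential expression calls.
* The fraction-explained bootstrap resamples points, not concentration
  levels; with few distinct doses the interval is approximate.
* Nuclear-fraction estimates assume equal fraction volumes and efficiencies;
  they are comparative (condition vs control), not absolute.
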