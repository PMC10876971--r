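---
title: "Detecting extrachromosomal DNA amplification from copy number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extrachromosomal DNA amplification from copy number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecamp)
library(data.table)
```

## The problem

Focal copy-number amplification in tumors comes in two mechanistically and
clinically distinct flavors: chromosomal amplification (homogeneously
staining regions, breakage-fusion-bridge products, tandem duplications) and
circular extrachromosomal DNA (ecDNA). ecDNA elements segregate randomly at
mitosis, reach extreme copy number quickly, carry amplified oncogenes with
unusually active chromatin, and mark tumors with poor prognosis. Direct
reconstruction of ecDNA structure needs whole-genome sequencing with
junction-spanning reads; most clinical cohorts only have whole-exome or
array data, from which allele-specific copy number profiles are routinely
produced (ASCAT and relatives). ecamp asks what those profiles alone can
say: given per-segment total and minor-allele copy number plus purity and
ploidy, which genes are ecDNA cargo, and which tumors harbor ecDNA at all?

Because ecDNA reconstruction is out of reach for exome data by design, the
package treats detection as supervised classification at the gene level,
followed by a rule-based typing layer that keeps every call anchored to
observable amplification.

## Feature model

Each (sample, gene) pair receives eleven features:

* `total_cn`, `minor_cn` — gene-level copy number, collapsed from segments.
  A gene takes the values of the overlapping segment with the largest
  overlap length; exact ties go to the segment with higher total copy
  number, which is the amplification-sensitive choice for a gene straddling
  an amplicon boundary. Genes with no overlapping segment stay missing, and
  missingness is preserved end to end — the boosted trees route missing
  values natively, nothing is imputed upstream.
* `purity`, `ploidy` — calibration factors carried per sample.
* `pLOH` — fraction of the covered autosomal genome with minor-allele copy
  number zero (and at least one total copy), a genome-instability summary.
  With tumor-only calling the minor allele is unknown; `pLOH` is then
  missing rather than zero.
* `AScore` — the number of non-acrocentric autosomal arms whose
  length-weighted mean copy number, rounded to the nearest integer, differs
  from the sample's rounded ploidy. The deviation baseline is
  ploidy-relative rather than fixed-diploid so whole-genome duplication does
  not saturate the score.
* `cna_burden` — the fraction of the covered autosomal genome whose total
  copy number deviates from the rounded ploidy.
* `freq_Circular`, `freq_BFB`, `freq_HR`, `freq_Linear` — per-gene
  frequencies of membership in circular, breakage-fusion-bridge, heavily
  rearranged, and linear amplicons in a reference amplicon catalog. Genes
  absent from the prior table get zero for all four.

Sex chromosomes are parsed and receive gene-level features, but are excluded
from the three genome-wide summaries so that gender does not shift the
genome-instability axis. One rounding convention (half away from zero) is
used everywhere a copy number or percentage is rounded.

## Classifier

Cargo genes are roughly 3-4 per thousand gene observations, so the training
protocol is built around that imbalance:

* **Grouped stratified cross-validation.** All rows of a tumor stay in one
  fold, because segment-level features are shared across a sample's genes
  and row-level splitting would leak. Folds are stratified by sample-level
  positivity (a sample is positive when it contains any cargo gene — the
  natural stratification unit at this prevalence), with positive and
  negative groups dealt round-robin after a seeded shuffle.
* **Average precision as the selection metric.** auPRC is the step-wise
  average precision, not trapezoidal interpolation of the PR curve, which is
  optimistic under heavy imbalance. Ties are grouped by threshold, so a
  constant score scores exactly the prevalence.
* **Random hyperparameter search with early stopping.** Each draw samples
  learning rate log-uniformly on [0.01, 0.3], tree depth 3-8, row and column
  subsampling on [0.5, 1], minimum child weight in {1, 5, 10}, and a
  positive-class weight of either 1 or the negative:positive ratio. Every
  draw is scored by k-fold CV in which each fold trains until `patience`
  (default 10) rounds pass without held-out auPRC improvement, up to
  `max_rounds`. The winning draw (best mean CV auPRC) is refit on all data
  for the mean stopped round count, and the refit configuration also
  produces out-of-fold probabilities so downstream evaluation does not touch
  in-sample scores.
* **Reference baseline.** A single-feature logistic regression on total copy
  number (median-imputed) exposes the same prediction interface; the boosted
  model is expected to beat it under the identical CV protocol, which is the
  package's standing regression test for "copy number is informative but not
  sufficient".

Determinism: one thread, an explicit seed for fold assignment, search draws
and boosting, and a saved RNG state around every seeded section, so the same
data and configuration give bit-identical CV histories.

## Three-class typing

Gene probability alone cannot distinguish "the model likes this gene" from
"this gene is actually amplified here", so calls are anchored to a focal
amplification predicate: `total_cn >= max(cn_min, ratio_min * ploidy)`, with
defaults `cn_min = 5` and `ratio_min = 2.25`. These defaults follow the
widely used amplicon-seeding convention of copy number above ~4.5 in a
near-diploid genome, scaled by ploidy; both are configuration options and
are recorded in every call file's metadata header. A gene is then

* `circular` — focally amplified and probability at or above `p_cut`
  (default 0.5, exposed as configuration);
* `noncircular` — focally amplified only;
* `nofocal` — everything else. A high-probability gene without observable
  amplification is deliberately vetoed to `nofocal`: the three classes stay
  mutually exclusive and grounded in copy number.

A sample is `circular` when it has at least one circular gene (those genes
are its cargo list, with no minimum cargo size — one amplified cargo gene
already means the tumor harbors ecDNA), else `noncircular` when any gene is,
else `nofocal`. Cytoband aggregation applies the same precedence over a
band's member genes. Raising `p_cut` can only shrink the circular set, which
the test suite checks as a monotonicity property.

## Downstream statistics

The cohort layer implements the analyses this kind of typing feeds:

* per-gene ordinary least squares of
  `TPM = a*CN + b*Circular + c*CancerType + d*TumorPurity + e`, with the
  two-sided p-value of `b` BH-adjusted across testable genes and an
  association flag at FDR < 0.05. The model is fit on TPM exactly as stated
  (a log-scale variant exists behind a flag but is off by default, since
  the linear form is the declared model);
* fold change in upper-quartile-normalized expression,
  `(TPM + 1) / mean(TPM + 1 over non-amplified samples of the same gene)`,
  and a nested-model F test comparing pooled versus class-specific
  fold-change-vs-CN lines;
* 2x2 odds ratios with either the cross-product estimator (all cells
  positive) or the conditional MLE of Fisher's exact test (sparse tables);
  mutual-exclusivity wrapping for sample-level flags such as ecDNA status
  versus MSI;
* fixed 1-Mb windowed class counts across the genome, with boundary-spanning
  entries counted in every window they touch;
* the stringent circular-DNA record filter: circle score > 50, discordant
  reads > 1, split reads >= 4, mean coverage > 4, coverage continuity < 0.1,
  region length (end - start) > 10 kb — strict and non-strict senses exactly
  as listed;
* cohort summaries with percentages printed to one decimal, half away from
  zero.

## The simulator

`simulate_cohort()` generates the statistical structure the classifier
assumes, with full ground truth. Per sample: purity uniform on (0.2, 1],
ploidy 2/3/4 (probabilities 0.7/0.2/0.1) with small jitter, a baseline
genome at rounded ploidy, per-arm gains/losses (rate 0.1 each), per-arm LOH
tracts (rate 0.15), and planted focal events: circular amplicons with copy
number uniform on [8, 100] and noncircular amplicons on [5, 12], each
covering a short run of adjacent genes. Both floors are raised to the
sample's focal-amplification threshold so that every planted event is
observable by the typing predicate — without this, a high-ploidy sample
could plant a copy number below its own calling threshold and the truth
labels would be unreachable by construction. The two copy-number ranges
deliberately overlap on [8, 12] so copy number alone cannot fully separate
the classes. Default rates (25% of samples with circular events, 25% with
noncircular, ~2 events of ~4-6 genes each) put the cargo-gene fraction at
roughly 0.3% of gene observations, the few-per-thousand regime the
classifier targets.

The prior table is derived from the simulated catalog itself — each gene's
frequency of circular (and noncircular, fed to the BFB slot) planting across
the cohort — mirroring how such priors are derived from reference amplicon
catalogs in practice. Expression is generated as
`TPM = 5*CN + 50*cargo + type offset + 10*purity + N(0, 10)`, truncated at
zero: a dosage slope of 5 TPM per copy with a cargo boost of 50 gives the
regression layer a signal comparable to a strongly ecDNA-responsive
oncogene, and three cancer-type offsets (0/20/40) exercise the categorical
adjustment.

What the simulator does **not** emulate: subclonal copy number, segmentation
noise and wavy baselines from real callers, GC/replication-timing artifacts,
breakpoint microhomology, or read-level data. Passing the recovery tests
therefore shows the pipeline is correct and well-calibrated under its own
assumptions — it does not certify performance on real tumor profiles, where
segmentation error and subclonality will erode both copy-number and prior
signals.

## Numerical and design choices

* Internal coordinates are 1-based inclusive (the segment-caller
  convention); BED input/output is converted at the boundary, and the
  conversion is an exact bijection.
* Chromosome names are normalized by stripping `chr` and upper-casing
  X/Y/MT; normalization is idempotent.
* Length arithmetic uses `end - start + 1`; all genome-fraction features are
  ratios of such lengths, making them invariant to coordinate scaling.
* Arm boundaries ship for hg38 with exact chromosome lengths and centromere
  midpoints accurate to about a megabase; acrocentric p-arms (13p, 14p, 15p,
  21p, 22p) are flagged and excluded from the aneuploidy score. The genome
  build of the gene model is the user's choice — annotation is an input, and
  hg38 resources are simply the packaged default.
* The packaged cytoband table is a constructed subset of recurrently
  amplified bands (see its `synthetic` filename); supply a full ideogram for
  production band-level work.
* Degenerate inputs have defined behavior rather than silent defaults:
  tumor-only profiles make `pLOH` missing (an error only when requested
  directly), a cutoff with no predicted positives reports missing precision,
  an all-constant copy-number baseline refuses to fit, empty gene-call sets
  type as `nofocal` with a warning, and zero cells push the odds ratio to
  the conditional MLE with an explicit error from the cross-product
  estimator.

## Problem sizes used by the test suite

The recovery checks run on a 200-sample x 1,000-gene simulated cohort with
20 random-search draws, 5 folds, and a 150-round ceiling — large enough for
the prevalence regime to be real (~550 cargo observations) while a full
train-evaluate cycle stays around a minute on one core. Unit tests use
smaller cohorts (30-60 samples, 100-200 genes) and brute-force oracles run
on profiles up to 1 Mb with at most 20 segments, where per-basepair
enumeration is exact and fast. The expression-regression checks use 500
samples per gene, where a 15% recovery band on the cargo coefficient is
comfortably within sampling error of the generating model.

## Known limitations

* The classifier inherits the label quality of whatever amplicon catalog
  produced its training truth; in the simulated setting truth is exact, in
  real use the labels are themselves computational calls.
* Breakage-fusion-bridge amplification with very high copy number is
  intrinsically hard to separate from ecDNA in coverage-derived features;
  the typing layer reports such genes as focally amplified either way, and
  the class boundary between `circular` and `noncircular` carries the
  model's uncertainty.
* Amplicon structure, junctions, and cargo-gene co-segregation are out of
  scope by design — the package types amplification, it does not reconstruct
  elements.
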