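# ecamp

Detection of extrachromosomal DNA (ecDNA) amplification from allele-specific
copy number profiles.

## What it is for

Tumors amplify oncogenes either on chromosomes (homogeneously staining
regions, breakage-fusion-bridge products) or on circular extrachromosomal
DNA. ecDNA segregates non-Mendelianly, reaches extreme copy number, and
marks aggressive disease — but reconstructing it directly requires
whole-genome sequencing, while most clinical cohorts have whole-exome or
array data. ecamp works from what those cohorts do have: allele-specific
copy number segment profiles (ASCAT-style `total_cn`/`minor_cn` segments
plus purity and ploidy per tumor). It is aimed at cancer-genomics analysts
who want gene-level ecDNA cargo predictions and sample-level
focal-amplification typing across a cohort, plus the standard downstream
association statistics.

## The method in brief

For every (sample, gene) pair, eleven features are engineered:

    total_cn, minor_cn, purity, ploidy,
    pLOH, AScore, cna_burden,
    freq_Circular, freq_BFB, freq_HR, freq_Linear

where `pLOH` is the autosomal genome fraction with minor-allele loss,
`AScore` counts chromosome arms whose rounded length-weighted copy number
deviates from rounded ploidy, `cna_burden` is the genome fraction deviating
from ploidy, and the four `freq_*` columns are per-gene amplicon-type
frequencies from a reference catalog. A gradient-boosted classifier
(XGBoost) is trained on these features under extreme class imbalance
(cargo genes are a few per thousand): grouped stratified k-fold CV so no
tumor's rows straddle folds, random hyperparameter search, early stopping
on held-out auPRC (step-wise average precision), and a refit at the best
configuration. Predictions are then anchored to observable amplification by
a three-class typing rule with predicate
`total_cn >= max(cn_min, ratio_min * ploidy)` (defaults 5 and 2.25):

* `circular` — focally amplified and cargo probability ≥ `p_cut`;
* `noncircular` — focally amplified only;
* `nofocal` — everything else (high probability without amplification is
  vetoed).

A sample is `circular` iff it has at least one circular gene (its cargo
list). Cohort statistics include per-gene expression regression
(`TPM = a*CN + b*Circular + c*CancerType + d*TumorPurity + e`, BH-FDR on
`b`), fold-change modelling with a nested-model F test, Fisher /
cross-product odds ratios and mutual exclusivity, 1-Mb windowed genome-wide
counts, circular-DNA record filtering, and cohort summaries. A simulator
generates cohorts with planted circular/noncircular amplicons, aneuploidy,
LOH, purity/ploidy variation and copy-number-coupled expression, with
complete ground truth.

## Worked example

```r
library(ecamp)
library(data.table)

cfg <- sim_config(n_samples = 60, n_genes = 150, n_chrom = 4,
                  rate_circular_sample = 0.4, rate_noncircular_sample = 0.3,
                  seed = 1)
cohort   <- simulate_cohort(cfg)
features <- sim_feature_table(cohort)       # 9,000 rows, cargo fraction 0.026

fit <- train_cargo_classifier(features, cargo_model_config(k_folds = 3, n_search = 3,
                                              patience = 5, max_rounds = 50,
                                              seed = 1))
fit
#> <cargo_classifier> 17-round booster, mean CV auPRC 0.953 (config 3 of 3), p_cut 0.50

round(sort(feature_importance(fit), decreasing = TRUE)[1:4], 3)
#>   total_cn     AScore cna_burden     purity
#>      0.671      0.076      0.057      0.055

calls   <- call_genes(features, predict_gene_prob(fit, features), p_cut = 0.5)
samples <- call_samples(calls)
cohort_summary(samples)
#>          klass count percent
#> 1:    circular    23    38.3
#> 2: noncircular    10    16.7
#> 3:     nofocal    27    45.0

mean(as.character(samples$klass) ==
     as.character(cohort$truth_samples[match(samples$sample_id, sample_id), klass]))
#> [1] 1
```

The classifier recovers the planted cargo genes (mean CV auPRC 0.95 on this
small cohort), copy number dominates the importance ranking as expected, and
the three-class typing reproduces the planted sample classes exactly. On the
default 200 x 1,000 cohort the gene-level CV auPRC is ~0.99, sample-level
auROC ~0.999, and the boosted model strictly beats a copy-number-only
logistic baseline under the same cross-validation protocol.

A command-line wrapper covering the same workflow
(`simulate`, `extract-features`, `train`, `predict`, `type`, `analyze`,
`filter-circleseq`) is installed as `exec/ecamp`.

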