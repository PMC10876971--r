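Package: ecamp
Title: Extrachromosomal DNA Amplification Detection from Allele-Specific
    Copy Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies extrachromosomal DNA (ecDNA) amplification in tumor
    genomes from allele-specific copy number segment profiles. Collapses
    region-level copy number to gene level, engineers an eleven-feature
    predictor set (copy numbers, purity, ploidy, genome-wide LOH fraction,
    aneuploidy score, copy-number alteration burden, and amplicon-frequency
    priors), trains a gradient-boosted cargo-gene classifier under extreme
    class imbalance with grouped stratified cross-validation and early
    stopping on the area under the precision-recall curve, and types tumors
    into a three-class focal-amplification system (circular, noncircular,
    nofocal). Includes downstream cohort statistics (ecDNA-associated
    oncogene regression, fold-change modelling, mutual-exclusivity odds
    ratios, windowed genome-wide frequencies, circular-DNA record filtering)
    and a synthetic-cohort simulator with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    xgboost,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
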