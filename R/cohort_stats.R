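# Downstream cohort statistics: ecDNA-associated oncogene regression,
# expression fold-change modelling, mutual-exclusivity odds ratios, windowed
# genome-wide signal, Circle-Map record filtering, and cohort summaries.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p_values numeric vector in \[0, 1\] (`NA` passed through).
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(p_values) {
  check_fraction(p_values, "p_values", allow_na = TRUE)
  p.adjust(p_values, method = "BH")
}

#' Per-gene ecDNA-association regression
#'
#' For each gene, fits the ordinary least squares model
#' `TPM = a*CN + b*Circular + c*CancerType + d*TumorPurity + e`
#' (cancer type as categorical contrasts) and tests whether residing on
#' ecDNA (`Circular`) shifts expression beyond the gene-dosage effect. The
#' two-sided p-value of `b` is BH-adjusted across all testable genes; a gene
#' is called ecDNA-associated when its FDR is below `fdr_cut`. Genes with a
#' single circular level, or with fewer observations than parameters, get a
#' missing p-value and are excluded from the FDR ranking.
#'
#' @param data long data.table with columns `sample_id`, `gene_id`, `TPM`,
#'   `CN`, `circular` (0/1), `cancer_type`, `purity`.
#' @param fdr_cut FDR threshold for the association flag.
#' @return data.table per gene: `gene_id`, `a`, `b`, `d`, `e`, `p_b`,
#'   `fdr_b`, `is_ecdna_associated`, plus a `cancer_type_coefs` list column
#'   of contrasts.
#' @export
ecdna_oncogene_regression <- function(data, fdr_cut = 0.05) {
  data <- as.data.table(data)
  req <- c("sample_id", "gene_id", "TPM", "CN", "circular", "cancer_type", "purity")
  miss <- setdiff(req, names(data))
  if (length(miss)) stopf("data lacks column(s): %s", paste(miss, collapse = ", "))
  fit_one <- function(sub) {
    sub <- sub[complete.cases(sub[, .(TPM, CN, circular, purity)])]
    multi_type <- length(unique(sub$cancer_type)) > 1
    n_par <- 3 + multi_type * (length(unique(sub$cancer_type)) - 1) + 1
    if (length(unique(sub$circular)) < 2 || nrow(sub) <= n_par) {
      return(data.table(a = NA_real_, b = NA_real_, d = NA_real_, e = NA_real_,
                        p_b = NA_real_, cancer_type_coefs = list(numeric())))
    }
    f <- if (multi_type) TPM ~ CN + circular + cancer_type + purity
         else TPM ~ CN + circular + purity
    fit <- lm(f, data = sub)
    cf <- summary(fit)$coefficients
    ct <- coef(fit)[grep("^cancer_type", names(coef(fit)))]
    data.table(a = unname(coef(fit)["CN"]), b = unname(coef(fit)["circular"]),
               d = unname(coef(fit)["purity"]), e = unname(coef(fit)["(Intercept)"]),
               p_b = if ("circular" %in% rownames(cf)) cf["circular", 4] else NA_real_,
               cancer_type_coefs = list(ct))
  }
  out <- data[, fit_one(.SD), by = gene_id]
  if (all(is.na(out$p_b))) stopf("no gene is testable for the circular effect")
  out[, fdr_b := benjamini_hochberg(p_b)]
  out[, is_ecdna_associated := !is.na(fdr_b) & fdr_b < fdr_cut]
  out[]
}

#' Fold change in upper-quartile-normalized expression
#'
#' For each amplified (gene, sample) pair: `(TPM + 1)` divided by the mean of
#' `(TPM + 1)` over all samples of the same cohort in which that gene is not
#' amplified. Genes without any non-amplified reference sample are skipped
#' (with a message).
#'
#' @param data data.table with `sample_id`, `gene_id`, `TPM`, `amplified`
#'   (logical).
#' @return data.table `gene_id`, `sample_id`, `fold_change` for amplified
#'   pairs.
#' @export
fold_change_uq <- function(data) {
  data <- as.data.table(data)
  req <- c("sample_id", "gene_id", "TPM", "amplified")
  miss <- setdiff(req, names(data))
  if (length(miss)) stopf("data lacks column(s): %s", paste(miss, collapse = ", "))
  out <- data[, {
    ref <- TPM[!amplified]
    if (!length(ref)) {
      message("gene ", gene_id[1], ": no non-amplified reference; skipped")
      NULL
    } else {
      denom <- mean(ref + 1)
      .(sample_id = sample_id[amplified],
        fold_change = (TPM[amplified] + 1) / denom)
    }
  }, by = gene_id]
  out[]
}

#' Compare fold-change-vs-CN lines between amplification classes
#'
#' Fits `fold_change = m*CN + b` per focal-amplification class and tests, by
#' an F test of the nested comparison (pooled slope/intercept versus
#' class-specific coefficients), whether the classes follow different lines.
#' This is how a transcriptional boost of circular over noncircular
#' amplification beyond gene dosage is assessed.
#'
#' @param fold_change numeric response.
#' @param cn copy number covariate.
#' @param klass class per point (e.g. `"circular"` / `"noncircular"`),
#'   exactly two or more levels, each with >= 3 points.
#' @return list of class `fold_change_fit`: per-class `slope`/`intercept`
#'   table, `F` statistic and `p` value.
#' @export
compare_fc_models <- function(fold_change, cn, klass) {
  dt <- data.table(fc = as.numeric(fold_change), cn = as.numeric(cn),
                   klass = as.character(klass))
  cnt <- dt[, .N, by = klass]
  if (nrow(cnt) < 2) stopf("need at least two classes, got %d", nrow(cnt))
  if (any(cnt$N < 3)) stopf("class '%s' has fewer than 3 points", cnt[N < 3]$klass[1])
  pooled <- lm(fc ~ cn, data = dt)
  full <- lm(fc ~ cn * klass, data = dt)
  av <- anova(pooled, full)
  fits <- dt[, {
    f <- lm(fc ~ cn, data = .SD)
    .(slope = unname(coef(f)["cn"]), intercept = unname(coef(f)["(Intercept)"]))
  }, by = klass]
  structure(list(per_class = fits[], F = av$F[2], p = av$`Pr(>F)`[2]),
            class = "fold_change_fit")
}

#' Odds ratio of a 2x2 contingency table
#'
#' @param a,b,c,d counts: exposed/event, exposed/non-event, unexposed/event,
#'   unexposed/non-event.
#' @param estimator `"cross_product"` — `(a*d)/(b*c)`, requiring all cells
#'   > 0 — or `"fisher_cmle"`, the conditional maximum-likelihood estimate
#'   of Fisher's exact test (usable with zero cells).
#' @return list `OR`, `p` (two-sided Fisher exact p), `table`.
#' @export
odds_ratio <- function(a, b, c, d, estimator = c("cross_product", "fisher_cmle")) {
  estimator <- match.arg(estimator)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stopf("contingency counts must be >= 0")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab)
  or <- if (estimator == "cross_product") {
    if (any(cells == 0))
      stopf("zero cell in 2x2 table; use estimator = 'fisher_cmle'")
    (a * d) / (b * c)
  } else unname(ft$estimate)
  list(OR = or, p = ft$p.value, table = tab)
}

#' Mutual exclusivity of two sample-level flags
#'
#' Cross-tabulates two aligned boolean vectors (e.g. ecDNA amplification and
#' MSI status) and delegates to [odds_ratio()]; an odds ratio below 1
#' indicates mutual exclusivity. Degenerate margins (a flag constant across
#' the cohort) are an error.
#'
#' @param flag_a,flag_b logical vectors, same length.
#' @param estimator passed to [odds_ratio()]; the conditional MLE default
#'   tolerates empty co-occurrence cells.
#' @return list `OR`, `p`, `table`.
#' @export
mutual_exclusivity <- function(flag_a, flag_b,
                               estimator = c("fisher_cmle", "cross_product")) {
  estimator <- match.arg(estimator)
  if (length(flag_a) != length(flag_b)) stopf("flags must align")
  if (all(flag_a) || !any(flag_a) || all(flag_b) || !any(flag_b))
    stopf("degenerate margin: a flag is constant across samples")
  odds_ratio(sum(flag_a & flag_b), sum(flag_a & !flag_b),
             sum(!flag_a & flag_b), sum(!flag_a & !flag_b),
             estimator = estimator)
}

#' Windowed genome-wide class frequency
#'
#' Tiles each chromosome with fixed windows starting at position 1 and
#' counts, per window and class, the entries overlapping it (an entry
#' spanning a window boundary is counted in every window it touches).
#' Windows with no entries are reported with zero counts.
#'
#' @param entries data.table `chrom`, `start`, `end`, `klass`.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window_size window width in bp (default 1 Mb).
#' @return data.table `chrom`, `window_start`, `window_end`,
#'   `circular_count`, `noncircular_count`.
#' @export
windowed_frequency <- function(entries, chrom_lengths, window_size = 1e6) {
  entries <- as.data.table(entries)
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  windows <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = window_size)
    data.table(chrom = ch, window_start = starts,
               window_end = pmin(starts + window_size - 1, chrom_lengths[[ch]]))
  }))
  windows[, `:=`(circular_count = 0L, noncircular_count = 0L)]
  if (nrow(entries)) {
    entries <- copy(entries)[, chrom := normalize_chrom(chrom)]
    unknown <- setdiff(entries$chrom, names(chrom_lengths))
    if (length(unknown)) stopf("entry on unknown chromosome %s", unknown[1])
    over <- entries[end > chrom_lengths[chrom] | start < 1]
    if (nrow(over))
      stopf("entry %s:%d-%d beyond chromosome end", over$chrom[1],
            as.integer(over$start[1]), as.integer(over$end[1]))
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(entries$chrom, IRanges::IRanges(entries$start, entries$end)),
      GenomicRanges::GRanges(windows$chrom,
                             IRanges::IRanges(windows$window_start, windows$window_end)))
    tab <- data.table(wi = S4Vectors::subjectHits(hits),
                      klass = as.character(entries$klass)[S4Vectors::queryHits(hits)])
    circ <- tab[klass == "circular", .N, by = wi]
    nonc <- tab[klass == "noncircular", .N, by = wi]
    if (nrow(circ)) windows[circ$wi, circular_count := circ$N]
    if (nrow(nonc)) windows[nonc$wi, noncircular_count := nonc$N]
  }
  windows[]
}

#' Filter Circle-Map records with the stringent circular-DNA criteria
#'
#' Keeps a record iff circle score > 50, more than one discordant read, at
#' least four split reads, mean coverage above 4, coverage continuity below
#' 0.1 (low values indicate near-contiguous coverage across the circle), and region
#' length (`end - start`) above 10 kb. Strict/non-strict senses follow the
#' criteria exactly; the filter is idempotent.
#'
#' @param records table from [read_circle_map()].
#' @return the surviving subset, same columns.
#' @export
filter_circle_map <- function(records) {
  records <- as.data.table(records)
  records[circle_score > 50 &
            discordant_reads > 1 &
            split_reads >= 4 &
            mean_coverage > 4 &
            coverage_continuity < 0.1 &
            (end - start) > 10000]
}

#' Cohort summary of focal-amplification classes
#'
#' @param sample_calls data.table with a `klass` column (one row per
#'   sample).
#' @return data.table `klass`, `count`, `percent` (percent of cohort, one
#'   decimal, half away from zero).
#' @export
cohort_summary <- function(sample_calls) {
  sample_calls <- as.data.table(sample_calls)
  if (!nrow(sample_calls)) stopf("empty cohort")
  n <- nrow(sample_calls)
  counts <- sample_calls[, .N, by = .(klass = factor(as.character(klass),
                                                     levels = FOCAL_CLASSES))]
  out <- merge(data.table(klass = factor(FOCAL_CLASSES, levels = FOCAL_CLASSES)),
               counts, by = "klass", all.x = TRUE)
  out[is.na(N), N := 0L]
  setnames(out, "N", "count")
  out[, percent := round_half_away(100 * count / n, 1)]
  setorder(out, klass)
  out[]
}
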