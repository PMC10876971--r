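# Downstream statistics: BH adjustment, per-gene expression regression,
# fold-change modelling, odds ratios, windowed signal, Circle-Map filtering
# and cohort summaries.

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.3)), "must lie in")
})

test_that("BH never decreases a p-value, stays capped, keeps sorted order", {
  set.seed(4)
  for (i in 1:10) {
    p <- sort(runif(20))
    adj <- benjamini_hochberg(p)
    expect_true(all(diff(adj) >= -1e-12))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  # constant vectors are fixed points of the step-up
  expect_equal(benjamini_hochberg(rep(0.37, 8)), rep(0.37, 8))
})

make_expression <- function(seed, n = 500, b = 50, noise_sd = 10,
                            genes_boosted = "G1", genes_null = character()) {
  set.seed(seed)
  all_genes <- c(genes_boosted, genes_null)
  data.table::rbindlist(lapply(all_genes, function(g) {
    cn <- sample(2:40, n, replace = TRUE)
    circ <- rbinom(n, 1, 0.15)
    type <- sample(c("typeA", "typeB"), n, replace = TRUE)
    purity <- runif(n, 0.3, 1)
    beff <- if (g %in% genes_boosted) b else 0
    data.table::data.table(
      sample_id = sprintf("S%03d", seq_len(n)), gene_id = g,
      TPM = pmax(0, 5 * cn + beff * circ + 20 * (type == "typeB") +
                   10 * purity + rnorm(n, 0, noise_sd)),
      CN = cn, circular = circ, cancer_type = type, purity = purity)
  }))
}

test_that("the per-gene regression recovers a planted ecDNA boost", {
  dat <- make_expression(1, n = 500, b = 50, noise_sd = 10,
                         genes_boosted = c("G1", "G2"), genes_null = "N1")
  res <- ecdna_oncogene_regression(dat)
  g1 <- res[gene_id == "G1"]
  expect_lt(abs(g1$b - 50) / 50, 0.15)
  expect_lt(g1$fdr_b, 0.05)
  expect_true(g1$is_ecdna_associated)
  expect_lt(abs(g1$a - 5) / 5, 0.25)
})

test_that("genes without a circular contrast get missing p, never a flag", {
  dat <- make_expression(2, n = 100, genes_boosted = "G1")
  flat <- data.table::copy(dat)[, `:=`(gene_id = "ALLNEG", circular = 0)]
  res <- ecdna_oncogene_regression(rbind(dat, flat))
  row <- res[gene_id == "ALLNEG"]
  expect_true(is.na(row$p_b))
  expect_false(row$is_ecdna_associated)
  only_flat <- data.table::copy(flat)
  expect_error(ecdna_oncogene_regression(only_flat), "no gene is testable")
})

test_that("fold change divides TPM+1 by the non-amplified reference mean", {
  dat <- data.table::data.table(
    sample_id = c("A", "B", "C"), gene_id = "MYC",
    TPM = c(9, 1, 3), amplified = c(TRUE, FALSE, FALSE))
  fc <- fold_change_uq(dat)
  expect_equal(fc$fold_change, 10 / 3)

  same <- data.table::data.table(sample_id = c("A", "B"), gene_id = "X",
                                 TPM = c(7, 7), amplified = c(TRUE, FALSE))
  expect_equal(fold_change_uq(same)$fold_change, 1)

  zero <- data.table::data.table(sample_id = c("A", "B"), gene_id = "X",
                                 TPM = c(0, 1), amplified = c(TRUE, FALSE))
  expect_equal(fold_change_uq(zero)$fold_change, 0.5)

  orphan <- data.table::data.table(sample_id = "A", gene_id = "X",
                                   TPM = 5, amplified = TRUE)
  expect_message(out <- fold_change_uq(orphan), "no non-amplified reference")
  expect_equal(nrow(out), 0)
})

test_that("the class F test separates different fold-change lines", {
  set.seed(9)
  n <- 100
  cn <- runif(2 * n, 5, 40)
  klass <- rep(c("circular", "noncircular"), each = n)
  slope <- ifelse(klass == "circular", 3, 1)
  fc <- slope * cn + 2 + rnorm(2 * n, 0, 1)
  fit <- compare_fc_models(fc, cn, klass)
  expect_lt(fit$p, 0.001)
  expect_equal(fit$per_class[klass == "circular", slope], 3, tolerance = 0.05)
  expect_equal(fit$per_class[klass == "noncircular", slope], 1, tolerance = 0.05)

  # per-class coefficients equal separately fitted least squares
  circ <- klass == "circular"
  sep <- stats::lm(fc[circ] ~ cn[circ])
  expect_equal(fit$per_class[klass == "circular", intercept],
               unname(coef(sep)[1]))
  expect_error(compare_fc_models(fc[circ], cn[circ], klass[circ]), "two classes")
  expect_error(compare_fc_models(fc[1:4], cn[1:4], c("a", "a", "b", "b")),
               "fewer than 3")
})

test_that("identical lines in both classes rarely reject", {
  rejections <- 0
  for (seed in 1:20) {
    set.seed(seed + 100)
    cn <- runif(60, 5, 40)
    klass <- rep(c("circular", "noncircular"), 30)
    fc <- 2 * cn + 1 + rnorm(60, 0, 2)
    fit <- compare_fc_models(fc, cn, klass)
    rejections <- rejections + (fit$p < 0.05)
  }
  expect_lte(rejections, 2)  # ~5% nominal over 20 null draws
})

test_that("odds ratios reproduce the printed cohort statistics", {
  # TP53 mutation in circular vs non-circular tumors: 101/164 vs 353/831
  tp53 <- odds_ratio(101, 63, 353, 478, estimator = "cross_product")
  expect_equal(round(tp53$OR, 2), 2.17)
  expect_lt(tp53$p, 0.001)
  # pseudogene table with sparse cells: conditional MLE as Fisher reports
  psg <- odds_ratio(7, 157, 7, 824, estimator = "fisher_cmle")
  expect_equal(round(psg$OR, 2), 5.24)
  expect_lt(psg$p, 0.01)
  # and the raw cross-product on the same table
  expect_equal(odds_ratio(7, 157, 7, 824, estimator = "cross_product")$OR,
               824 / 157)
  expect_equal(odds_ratio(1, 1, 1, 1)$OR, 1)
  expect_error(odds_ratio(0, 5, 3, 2), "fisher_cmle")
})

test_that("cross-product OR is symmetric under row/column swaps", {
  set.seed(31)
  for (i in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    or <- odds_ratio(cells[1], cells[2], cells[3], cells[4])$OR
    both <- odds_ratio(cells[4], cells[3], cells[2], cells[1])$OR
    rows <- odds_ratio(cells[3], cells[4], cells[1], cells[2])$OR
    expect_equal(or, both)
    expect_equal(rows, 1 / or)
  }
})

test_that("mutual exclusivity flags anti-co-occurring alterations", {
  a <- rep(c(TRUE, FALSE), times = c(30, 70))
  b <- rep(c(FALSE, TRUE, FALSE), times = c(30, 30, 40))
  me <- mutual_exclusivity(a, b)
  expect_lt(me$OR, 1)
  expect_lt(me$p, 0.05)
  expect_error(mutual_exclusivity(rep(TRUE, 5), c(TRUE, rep(FALSE, 4))),
               "degenerate margin")
})

test_that("windowed counts tile the genome and conserve entry mass", {
  lens <- c("1" = 3e6)
  one <- data.table::data.table(chrom = "1", start = 500001, end = 600000,
                                klass = "circular")
  w <- windowed_frequency(one, lens)
  expect_equal(nrow(w), 3)
  expect_equal(w$circular_count, c(1L, 0L, 0L))

  spanning <- data.table::data.table(chrom = "1", start = 999001, end = 1001000,
                                     klass = "noncircular")
  w2 <- windowed_frequency(spanning, lens)
  expect_equal(w2$noncircular_count, c(1L, 1L, 0L))

  empty <- windowed_frequency(one[0], lens)
  expect_true(all(empty$circular_count == 0) && all(empty$noncircular_count == 0))

  # mass conservation for entries inside single windows
  set.seed(13)
  starts <- sample(seq(1, 2.9e6, by = 1e4), 40)
  ents <- data.table::data.table(chrom = "1", start = starts,
                                 end = pmin(starts + 5e3, 3e6),
                                 klass = sample(c("circular", "noncircular"),
                                                40, replace = TRUE))
  w3 <- windowed_frequency(ents, lens)
  expect_equal(sum(w3$circular_count) + sum(w3$noncircular_count), 40L)

  beyond <- data.table::data.table(chrom = "1", start = 2.9e6, end = 3.5e6,
                                   klass = "circular")
  expect_error(windowed_frequency(beyond, lens), "beyond chromosome end")
})

test_that("the Circle-Map filter applies every criterion at its boundary", {
  base <- data.table::data.table(
    chrom = "1", start = 0, end = 20000, discordant_reads = 2, split_reads = 4,
    circle_score = 60, mean_coverage = 5, coverage_sd = 1,
    coverage_continuity = 0.05)
  recs <- data.table::rbindlist(list(
    base,
    data.table::copy(base)[, circle_score := 50],          # strict >
    data.table::copy(base)[, discordant_reads := 1],       # strict >
    data.table::copy(base)[, split_reads := 3],            # >= 4
    data.table::copy(base)[, coverage_continuity := 0.1],  # strict <
    data.table::copy(base)[, end := 10000]))               # length strict >
  kept <- filter_circle_map(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$circle_score, 60)
  # subset of input and idempotent
  expect_identical(filter_circle_map(kept), kept)
})

test_that("cohort summaries reproduce the printed CRC percentages", {
  klass <- rep(c("circular", "noncircular", "nofocal"),
               times = c(164, 246, 1015 - 164 - 246))
  summ <- cohort_summary(data.table::data.table(klass = klass))
  expect_equal(summ[klass == "circular", count], 164L)
  expect_equal(summ[klass == "circular", percent], 16.2)
  expect_equal(summ[klass == "noncircular", percent], 24.2)
  expect_equal(sum(summ$count), 1015L)

  none <- cohort_summary(data.table::data.table(klass = rep("nofocal", 10)))
  expect_equal(none[klass == "circular", percent], 0)
  expect_error(cohort_summary(data.table::data.table()), "empty cohort")
})
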