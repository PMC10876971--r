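# Gene-level collapsing and the genome-wide summary features, checked
# against hand-derived values and brute-force per-basepair oracles.

prof1 <- function() {
  sample_profile("P1", data.table::data.table(
    chrom = c("1", "2"), start = c(1, 1), end = c(1e8, 5e7),
    total_cn = c(2L, 2L), minor_cn = c(1L, 0L)), purity = 0.9, ploidy = 2)
}

test_that("gene collapsing picks the max-overlap segment, ties to higher CN", {
  p <- sample_profile("S", data.table::data.table(
    chrom = "1", start = c(1, 1501), end = c(1500, 10000),
    total_cn = c(8L, 2L), minor_cn = c(1L, 1L)))
  genes <- data.table::data.table(gene_id = "G", chrom = "1",
                                  start = 1000, end = 2000, strand = ".")
  # overlaps: 501 bp with CN 8 vs 500 bp with CN 2
  cn <- collapse_to_gene_cn(p, genes)
  expect_equal(cn$total_cn, 8L)

  # full containment
  p2 <- sample_profile("S2", data.table::data.table(
    chrom = "1", start = 1, end = 10000, total_cn = 5L, minor_cn = 1L))
  expect_equal(collapse_to_gene_cn(p2, genes)$total_cn, 5L)
  expect_equal(collapse_to_gene_cn(p2, genes)$minor_cn, 1L)

  # exact tie in overlap -> the amplified segment wins
  p3 <- sample_profile("S3", data.table::data.table(
    chrom = "1", start = c(1, 1501), end = c(1500, 3000),
    total_cn = c(2L, 9L), minor_cn = c(1L, 1L)))
  g3 <- data.table::data.table(gene_id = "G", chrom = "1",
                               start = 1001, end = 2000, strand = ".")
  expect_equal(collapse_to_gene_cn(p3, g3)$total_cn, 9L)

  # gene on an uncovered chromosome stays missing
  g4 <- data.table::data.table(gene_id = "G4", chrom = "7",
                               start = 1, end = 100, strand = ".")
  expect_true(is.na(collapse_to_gene_cn(p2, g4)$total_cn))
})

test_that("pLOH is the LOH length fraction of the covered autosomal genome", {
  expect_equal(compute_ploh(prof1()), 5e7 / 1.5e8)
  all_loh <- sample_profile("L", data.table::data.table(
    chrom = "1", start = 1, end = 1000, total_cn = 2L, minor_cn = 0L))
  expect_equal(compute_ploh(all_loh), 1)
  no_loh <- sample_profile("N", data.table::data.table(
    chrom = "1", start = 1, end = 1000, total_cn = 2L, minor_cn = 1L))
  expect_equal(compute_ploh(no_loh), 0)
  tumor_only <- sample_profile("T", data.table::data.table(
    chrom = "1", start = 1, end = 1000, total_cn = 2L, minor_cn = NA_integer_))
  expect_error(compute_ploh(tumor_only), "tumor-only")
})

test_that("aneuploidy score counts arms deviating from rounded ploidy", {
  arms <- small_arm_table()
  p <- sample_profile("A", data.table::data.table(
    chrom = "1", start = c(1, 400001), end = c(400000, 1e6),
    total_cn = c(3L, 2L), minor_cn = c(1L, 1L)), ploidy = 2)
  expect_equal(compute_aneuploidy_score(p, arms), 1L)

  dip <- sample_profile("D", data.table::data.table(
    chrom = c("1", "2"), start = 1, end = 1e6,
    total_cn = 2L, minor_cn = 1L), ploidy = 2)
  expect_equal(compute_aneuploidy_score(dip, arms), 0L)

  wgd <- sample_profile("W", data.table::data.table(
    chrom = c("1", "2"), start = 1, end = 1e6,
    total_cn = 4L, minor_cn = 2L), ploidy = 4)
  expect_equal(compute_aneuploidy_score(wgd, arms), 0L)
})

test_that("cna_burden is the ploidy-deviant length fraction", {
  p <- sample_profile("B", data.table::data.table(
    chrom = c("1", "2"), start = 1, end = c(1e8, 5e7),
    total_cn = c(2L, 3L), minor_cn = c(1L, 1L)), ploidy = 2)
  expect_equal(compute_cna_burden(p), 5e7 / 1.5e8)
  expect_equal(compute_cna_burden(prof1()), 0)
  all_dev <- sample_profile("AD", data.table::data.table(
    chrom = "1", start = 1, end = 1000, total_cn = 5L, minor_cn = 1L), ploidy = 2)
  expect_equal(compute_cna_burden(all_dev), 1)
})

test_that("summary features match per-bp brute force on random profiles", {
  arms <- small_arm_table()
  for (seed in 1:30) {
    p <- random_small_profile(seed)
    expect_equal(compute_ploh(p), ploh_oracle(p), info = paste("seed", seed))
    expect_equal(compute_cna_burden(p), burden_oracle(p), info = paste("seed", seed))
    expect_equal(compute_aneuploidy_score(p, arms), ascore_oracle(p, arms),
                 info = paste("seed", seed))
  }
})

test_that("gene collapsing matches exhaustive overlap enumeration", {
  for (seed in 1:30) {
    p <- random_small_profile(seed)
    g <- random_genes(seed)
    expect_equal(collapse_to_gene_cn(p, g), collapse_oracle(p, g),
                 info = paste("seed", seed))
  }
})

test_that("summary features are invariant to coordinate scaling", {
  p <- random_small_profile(11)
  scaled_seg <- data.table::copy(p$segments)
  scaled_seg[, `:=`(start = (start - 1) * 10 + 1, end = end * 10)]
  ps <- sample_profile("SC", scaled_seg, purity = p$purity, ploidy = p$ploidy)
  expect_equal(compute_ploh(ps), compute_ploh(p))
  expect_equal(compute_cna_burden(ps), compute_cna_burden(p))
  arms <- small_arm_table()
  arms10 <- data.table::copy(arms)[, `:=`(start = (start - 1) * 10 + 1, end = end * 10)]
  expect_equal(compute_aneuploidy_score(ps, arms10),
               compute_aneuploidy_score(p, arms))
})

test_that("summary fractions stay in range and AScore within arm count", {
  arms <- small_arm_table()
  for (seed in 31:60) {
    p <- random_small_profile(seed)
    expect_gte(compute_ploh(p), 0); expect_lte(compute_ploh(p), 1)
    b <- compute_cna_burden(p)
    expect_gte(b, 0); expect_lte(b, 1)
    a <- compute_aneuploidy_score(p, arms)
    expect_gte(a, 0); expect_lte(a, nrow(arms))
  }
})

test_that("the feature matrix has one row per (sample, gene) with 11 slots", {
  profs <- list(prof1(), sample_profile("P2", data.table::data.table(
    chrom = "1", start = 1, end = 1e8, total_cn = 4L, minor_cn = 1L),
    purity = 0.5, ploidy = 2))
  genes <- data.table::data.table(
    gene_id = c("A", "B", "C"), chrom = "1",
    start = c(100, 2e7, 9e7), end = c(2000, 2.1e7, 9.1e7), strand = ".")
  priors <- data.table::data.table(gene_id = "A", freq_Circular = 0.2,
                                   freq_BFB = 0.1, freq_HR = 0, freq_Linear = 0.05)
  fm <- build_feature_matrix(profs, genes, priors, arms = small_arm_table())
  expect_equal(nrow(fm), 6)
  expect_equal(setdiff(names(fm), c("sample_id", "gene_id")),
               c("total_cn", "minor_cn", "purity", "ploidy", "pLOH", "AScore",
                 "cna_burden", "freq_Circular", "freq_BFB", "freq_HR", "freq_Linear"))
  # absent gene -> zero priors; present gene -> its values
  expect_equal(fm[gene_id == "B", unique(freq_Circular)], 0)
  expect_equal(fm[gene_id == "A", unique(freq_Circular)], 0.2)
  # sample-level features constant within a sample
  per <- fm[, .(n_ploh = data.table::uniqueN(pLOH),
                n_burden = data.table::uniqueN(cna_burden)), by = sample_id]
  expect_true(all(per$n_ploh == 1) && all(per$n_burden == 1))
  expect_error(build_feature_matrix(list(), genes, priors), "empty")
})

test_that("tumor-only profiles yield NA pLOH in the matrix, not an error", {
  p <- sample_profile("TO", data.table::data.table(
    chrom = "1", start = 1, end = 1e6, total_cn = 4L, minor_cn = NA_integer_))
  genes <- data.table::data.table(gene_id = "A", chrom = "1",
                                  start = 100, end = 2000, strand = ".")
  priors <- data.table::data.table(gene_id = character(), freq_Circular = numeric(),
                                   freq_BFB = numeric(), freq_HR = numeric(),
                                   freq_Linear = numeric())
  fm <- build_feature_matrix(list(p), genes, priors, arms = small_arm_table())
  expect_true(is.na(fm$pLOH))
  expect_true(is.na(fm$minor_cn))
  expect_equal(fm$total_cn, 4L)
})
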