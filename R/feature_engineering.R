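# Gene-level feature engineering: collapse segment copy number onto genes,
# compute the genome-wide summary features (pLOH, aneuploidy score, CNA
# burden), and assemble the 11-feature matrix the classifier consumes.
# Sample-level genome summaries use autosomes only; gene-level copy number
# is still computed on X/Y.

FEATURE_COLS <- c("total_cn", "minor_cn", "purity", "ploidy", "pLOH",
                  "AScore", "cna_burden", "freq_Circular", "freq_BFB",
                  "freq_HR", "freq_Linear")

seg_granges <- function(seg) {
  GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
}

#' Collapse segment copy number to gene level
#'
#' Each gene receives the `(total_cn, minor_cn)` of the overlapping segment
#' with the largest overlap length; ties are broken in favor of the higher
#' total copy number (amplification-sensitive). Genes overlapping no segment
#' get missing copy number.
#'
#' @param profile a [sample_profile()].
#' @param genes gene annotation from [read_gene_bed()].
#' @return data.table `gene_id`, `total_cn`, `minor_cn` (one row per gene,
#'   in the order of `genes`; `NA` where no segment overlaps).
#' @export
collapse_to_gene_cn <- function(profile, genes) {
  genes <- as.data.table(genes)
  out <- data.table(gene_id = genes$gene_id,
                    total_cn = NA_integer_, minor_cn = NA_integer_)
  seg <- profile$segments
  if (!nrow(seg) || !nrow(genes)) return(out[])
  # restrict to chromosomes the profile covers (keeps GRanges seqlevels
  # aligned; genes elsewhere simply stay missing)
  shared <- genes$chrom %in% unique(seg$chrom)
  if (!any(shared)) return(out[])
  gsub_ <- genes[shared]
  hits <- GenomicRanges::findOverlaps(seg_granges(gsub_), seg_granges(seg))
  if (!length(hits)) return(out[])
  gi <- which(shared)[S4Vectors::queryHits(hits)]
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(genes$end[gi], seg$end[si]) - pmax(genes$start[gi], seg$start[si]) + 1
  cand <- data.table(gi = gi, ov = ov,
                     total_cn = seg$total_cn[si], minor_cn = seg$minor_cn[si])
  setorder(cand, gi, -ov, -total_cn, na.last = TRUE)
  best <- cand[, .SD[1], by = gi]
  out[best$gi, `:=`(total_cn = best$total_cn, minor_cn = best$minor_cn)]
  out[]
}

autosomal_segments <- function(profile) {
  profile$segments[is_autosome(chrom)]
}

#' Genome fraction with loss of heterozygosity
#'
#' pLOH is the fraction of the covered autosomal genome whose minor allele is
#' lost: sum of lengths of autosomal segments with `minor_cn == 0` and
#' `total_cn >= 1`, divided by the summed length of all autosomal segments
#' (length = end - start + 1). Segments with missing `minor_cn` are excluded
#' from both sums; if every autosomal segment lacks `minor_cn` (tumor-only
#' calling), pLOH is unavailable and an error is raised.
#'
#' @param profile a [sample_profile()].
#' @return fraction in \[0, 1\].
#' @export
compute_ploh <- function(profile) {
  seg <- autosomal_segments(profile)[!is.na(minor_cn)]
  if (!nrow(seg))
    stopf("pLOH unavailable for tumor-only input (sample %s)", profile$sample_id)
  len <- seg$end - seg$start + 1
  loh <- seg$minor_cn == 0 & seg$total_cn >= 1
  sum(len[loh]) / sum(len)
}

#' Arm-level aneuploidy score
#'
#' For each non-excluded autosomal arm, the length-weighted mean total copy
#' number over the segments overlapping the arm is rounded to the nearest
#' integer (half away from zero); the arm counts as aberrant when that
#' integer differs from the sample's rounded ploidy. The score is the number
#' of aberrant arms. Arms with no covered length are skipped.
#'
#' @param profile a [sample_profile()].
#' @param arms arm table from [load_arm_table()].
#' @return integer count of aberrant arms.
#' @export
compute_aneuploidy_score <- function(profile, arms = load_arm_table()) {
  arms <- as.data.table(arms)[excluded == FALSE & is_autosome(chrom)]
  seg <- autosomal_segments(profile)
  baseline <- round_half_away(profile$ploidy)
  if (!nrow(seg)) return(0L)
  hits <- GenomicRanges::findOverlaps(seg_granges(arms), seg_granges(seg))
  if (!length(hits)) return(0L)
  ai <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- pmin(arms$end[ai], seg$end[si]) - pmax(arms$start[ai], seg$start[si]) + 1
  cand <- data.table(ai = ai, w = w, cn = seg$total_cn[si])
  armcn <- cand[, .(cn = round_half_away(sum(w * cn) / sum(w))), by = ai]
  as.integer(sum(armcn$cn != baseline))
}

#' Copy number alteration burden
#'
#' Fraction of the covered autosomal genome whose total copy number deviates
#' from the sample's rounded ploidy (deviation baseline `round(ploidy)`,
#' half away from zero).
#'
#' @param profile a [sample_profile()].
#' @return fraction in \[0, 1\].
#' @export
compute_cna_burden <- function(profile) {
  seg <- autosomal_segments(profile)
  if (!nrow(seg)) return(0)
  len <- seg$end - seg$start + 1
  sum(len[seg$total_cn != round_half_away(profile$ploidy)]) / sum(len)
}

#' Sample-level summary features
#'
#' Purity, ploidy, pLOH, aneuploidy score and CNA burden for one profile.
#' pLOH is `NA` (not an error) when minor-allele copy number is unavailable,
#' matching the tumor-only calling path where downstream models route
#' missing values natively.
#'
#' @inheritParams compute_aneuploidy_score
#' @return one-row data.table `purity`, `ploidy`, `pLOH`, `AScore`,
#'   `cna_burden`.
#' @export
sample_summary_features <- function(profile, arms = load_arm_table()) {
  ploh <- tryCatch(compute_ploh(profile), error = function(e) NA_real_)
  data.table(purity = profile$purity, ploidy = profile$ploidy, pLOH = ploh,
             AScore = compute_aneuploidy_score(profile, arms),
             cna_burden = compute_cna_burden(profile))
}

#' Build the 11-feature matrix for a cohort
#'
#' One row per (sample, gene): gene-level `total_cn`/`minor_cn` from
#' [collapse_to_gene_cn()], the five sample summaries replicated across the
#' sample's genes, and the four amplicon-frequency priors joined by gene
#' (absent genes get 0). Missing copy number is preserved as `NA`, never
#' imputed here.
#'
#' @param profiles list of [sample_profile()] objects.
#' @param genes gene annotation table.
#' @param priors prior table from [read_priors()] (or compatible).
#' @param restrict_to optional character vector of gene ids to keep.
#' @param arms arm table for the aneuploidy score.
#' @return data.table with `sample_id`, `gene_id` and the 11 feature columns
#'   in fixed order.
#' @export
build_feature_matrix <- function(profiles, genes, priors,
                                 restrict_to = NULL, arms = load_arm_table()) {
  if (!length(profiles)) stopf("empty profile list")
  genes <- as.data.table(genes)
  if (!is.null(restrict_to)) genes <- genes[gene_id %in% restrict_to]
  pri <- prior_lookup(priors, genes$gene_id)
  rows <- lapply(profiles, function(p) {
    cn <- collapse_to_gene_cn(p, genes)
    cbind(data.table(sample_id = p$sample_id), cn,
          sample_summary_features(p, arms),
          pri[, -"gene_id"])
  })
  out <- rbindlist(rows)
  setcolorder(out, c("sample_id", "gene_id", FEATURE_COLS))
  out[]
}
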