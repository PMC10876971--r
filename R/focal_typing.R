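# Three-class focal-amplification typing. A gene (or tumor) is 'circular'
# when the classifier calls it a cargo gene AND it is focally amplified;
# 'noncircular' when focally amplified only; 'nofocal' otherwise. A high
# cargo probability without observable focal amplification is vetoed to
# nofocal so the classes stay mutually exclusive and anchored to copy
# number. Precedence circular > noncircular > nofocal everywhere.

FOCAL_CLASSES <- c("circular", "noncircular", "nofocal")

#' Focal-amplification predicate
#'
#' A copy number counts as focally amplified when
#' `total_cn >= max(cn_min, ratio_min * ploidy)`. The defaults (`cn_min = 5`,
#' `ratio_min = 2.25`) follow the common amplicon-seeding convention of
#' copy number above ~4.5 in a near-diploid genome, scaled by ploidy.
#' Missing copy number is never amplified.
#'
#' @param total_cn integer copy number (may be `NA`).
#' @param ploidy sample ploidy.
#' @param cn_min absolute copy-number floor.
#' @param ratio_min ploidy multiple floor.
#' @return logical vector.
#' @export
is_focally_amplified <- function(total_cn, ploidy, cn_min = 5, ratio_min = 2.25) {
  amp <- total_cn >= pmax(cn_min, ratio_min * ploidy)
  amp[is.na(amp)] <- FALSE
  amp
}

#' Gene-level three-class calls
#'
#' @param features data.table with `sample_id`, `gene_id`, `total_cn`,
#'   `ploidy` (one row per (sample, gene)).
#' @param probabilities cargo-gene probabilities aligned with `features`.
#' @param p_cut probability cutoff in (0, 1).
#' @param cn_min,ratio_min see [is_focally_amplified()].
#' @return data.table `sample_id`, `gene_id`, `probability`, `total_cn`,
#'   `ploidy`, `klass` (factor over circular/noncircular/nofocal).
#' @export
call_genes <- function(features, probabilities, p_cut = 0.5,
                       cn_min = 5, ratio_min = 2.25) {
  if (p_cut <= 0 || p_cut >= 1) stopf("p_cut must lie in (0, 1)")
  features <- as.data.table(features)
  if (length(probabilities) != nrow(features))
    stopf("probabilities must align with feature rows")
  amp <- is_focally_amplified(features$total_cn, features$ploidy, cn_min, ratio_min)
  klass <- fifelse(amp & probabilities >= p_cut, "circular",
                   fifelse(amp, "noncircular", "nofocal"))
  data.table(sample_id = features$sample_id, gene_id = features$gene_id,
             probability = probabilities,
             total_cn = features$total_cn, ploidy = features$ploidy,
             klass = factor(klass, levels = FOCAL_CLASSES))[]
}

#' Sample-level call from its gene calls
#'
#' Precedence: a sample with any circular gene is circular and those genes
#' become its cargo list; otherwise noncircular if any noncircular gene;
#' otherwise nofocal. The cargo list is non-empty iff the class is circular.
#'
#' @param gene_calls rows of [call_genes()] for one sample.
#' @return one-row data.table `sample_id`, `klass`, `cargo_genes` (list
#'   column).
#' @export
call_sample <- function(gene_calls) {
  gene_calls <- as.data.table(gene_calls)
  if (!nrow(gene_calls)) {
    warnf("empty gene call set; returning nofocal")
    return(data.table(sample_id = NA_character_,
                      klass = factor("nofocal", levels = FOCAL_CLASSES),
                      cargo_genes = list(character())))
  }
  sid <- unique(gene_calls$sample_id)
  if (length(sid) != 1) stopf("call_sample expects a single sample's calls")
  cargo <- gene_calls[klass == "circular", gene_id]
  k <- if (length(cargo)) "circular"
       else if (any(gene_calls$klass == "noncircular")) "noncircular"
       else "nofocal"
  data.table(sample_id = sid, klass = factor(k, levels = FOCAL_CLASSES),
             cargo_genes = list(as.character(cargo)))
}

#' Sample calls for a whole cohort
#'
#' @param gene_calls [call_genes()] output for many samples.
#' @return data.table with one row per sample.
#' @export
call_samples <- function(gene_calls) {
  gene_calls <- as.data.table(gene_calls)
  rbindlist(lapply(split(gene_calls, by = "sample_id"), call_sample))
}

#' Aggregate gene calls to cytobands
#'
#' Per (sample, cytoband), the class is the maximum-precedence class among
#' the member genes; bands with no overlapping called gene are absent from
#' the output. Genes falling outside every band are skipped.
#'
#' @param gene_calls [call_genes()] output.
#' @param genes gene annotation (for coordinates).
#' @param cytobands table from [load_cytoband_table()].
#' @return data.table `sample_id`, `cytoband`, `klass`, `genes` (list of
#'   supporting gene ids).
#' @export
aggregate_to_cytoband <- function(gene_calls, genes, cytobands = load_cytoband_table()) {
  gene_calls <- as.data.table(gene_calls)
  genes <- as.data.table(genes)
  cytobands <- as.data.table(cytobands)
  gpos <- genes[, .(gene_id, chrom, start, end)]
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(gpos$chrom, IRanges::IRanges(gpos$start, gpos$end)),
    GenomicRanges::GRanges(cytobands$chrom, IRanges::IRanges(cytobands$start, cytobands$end)))
  band_of <- data.table(gene_id = gpos$gene_id[S4Vectors::queryHits(hits)],
                        cytoband = cytobands$cytoband[S4Vectors::subjectHits(hits)])
  joined <- merge(gene_calls, band_of, by = "gene_id", allow.cartesian = TRUE)
  if (!nrow(joined))
    return(data.table(sample_id = character(), cytoband = character(),
                      klass = factor(character(), levels = FOCAL_CLASSES),
                      genes = list()))
  joined[, rank := match(as.character(klass), FOCAL_CLASSES)]
  out <- joined[, {
    best <- min(rank)
    .(klass = factor(FOCAL_CLASSES[best], levels = FOCAL_CLASSES),
      genes = list(gene_id[rank == best]))
  }, by = .(sample_id, cytoband)]
  setorder(out, sample_id, cytoband)
  out[]
}
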