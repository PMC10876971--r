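# Packaged genome-resource tables and their loaders. Arm boundaries use the
# exact hg38 chromosome lengths with centromere midpoints accurate to band
# resolution (~1 Mb); the packaged cytoband table is a constructed subset of
# recurrently amplified bands (see file name), intended for examples and
# testing — supply a full ideogram table for production cytoband work.

#' Load a chromosome-arm table
#'
#' Arm tables drive the aneuploidy score: each row is one arm with 1-based
#' inclusive coordinates, arms partition their chromosome (p end + 1 = q
#' start), and acrocentric p-arms (13p, 14p, 15p, 21p, 22p) are flagged
#' `excluded` so genome-wide scores skip them.
#'
#' @param path TSV with columns `chrom`, `arm`, `start`, `end`, `excluded`;
#'   `NULL` loads the packaged hg38 table.
#' @return data.table with the five columns, chromosome names normalized.
#' @export
load_arm_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "arms_hg38.tsv", package = "ecamp")
  dt <- read_tsv_checked(path, c("chrom", "arm", "start", "end", "excluded"),
                         "arm table")
  dt[, chrom := normalize_chrom(chrom)]
  dt[, `:=`(start = as.numeric(start), end = as.numeric(end),
            excluded = as.logical(as.integer(excluded)))]
  bad <- dt[, .(ok = all(start[order(start)][-1] == head(end[order(start)], -1) + 1)),
            by = chrom][ok == FALSE]
  if (nrow(bad)) stopf("arm table: arms do not partition chromosome %s", bad$chrom[1])
  dt[]
}

#' Load a cytoband table
#'
#' @param path TSV with columns `cytoband`, `chrom`, `start`, `end`; `NULL`
#'   loads the packaged synthetic subset of recurrent amplicon bands
#'   (approximate hg38 boundaries — adequate for demonstration, not for
#'   fine-mapped band assignment).
#' @return data.table with the four columns, chromosome names normalized.
#' @export
load_cytoband_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cytobands_hg38_synthetic.tsv", package = "ecamp")
  dt <- read_tsv_checked(path, c("cytoband", "chrom", "start", "end"),
                         "cytoband table")
  dt[, chrom := normalize_chrom(chrom)]
  dt[, `:=`(start = as.numeric(start), end = as.numeric(end))]
  dt[]
}
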