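# Shared helpers: chromosome-name normalization, rounding convention,
# small validators used across modules.

#' Normalize chromosome names
#'
#' Strips any `"chr"` prefix and upper-cases sex/mitochondrial names so that
#' `"chr8"` and `"8"` (or `"chrx"` and `"X"`) map to the same key. The
#' operation is idempotent.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names (`"1"`..`"22"`, `"X"`, `"Y"`,
#'   `"MT"`).
#' @examples
#' normalize_chrom(c("chr8", "8", "chrX", "chrM"))
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

AUTOSOMES <- as.character(1:22)

is_autosome <- function(chrom) normalize_chrom(chrom) %in% AUTOSOMES

#' Round half away from zero
#'
#' The rounding convention used throughout the package (ploidy baselines,
#' reported percentages): ties round away from zero, so `round_half_away(2.5)`
#' is 3 and `round_half_away(-2.5)` is -3. This differs from base R's
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded at `digits`.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, allow_na = FALSE) {
  bad <- if (allow_na) x[!is.na(x)] else x
  if (!allow_na && anyNA(x)) stopf("%s contains missing values", name)
  lo_ok <- if (lo_open) bad > lo else bad >= lo
  if (any(!lo_ok | bad > hi)) {
    stopf("%s must lie in %s%g, %g]: offending value %g",
          name, if (lo_open) "(" else "[", lo, hi,
          bad[which(!lo_ok | bad > hi)[1]])
  }
  invisible(x)
}

# Order rows of a segment-like data.table by (chrom, start) with numeric
# chromosomes before X/Y/MT.
chrom_rank <- function(chrom) {
  x <- normalize_chrom(chrom)
  r <- suppressWarnings(as.integer(x))
  r[x == "X"] <- 23L
  r[x == "Y"] <- 24L
  r[x == "MT"] <- 25L
  r
}
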