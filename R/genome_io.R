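# Ingestion of the tabular genomic formats the framework consumes:
# ASCAT-style / SEG segment tables, BED gene models, amplicon-frequency
# priors, Circle-Map Realign records, and the call tables it emits.
# Internal coordinates are 1-based inclusive throughout (ASCAT convention);
# BED is converted at the boundary.

#' Construct a sample profile
#'
#' A sample profile holds one tumor's allele-specific copy number segments
#' together with its purity, ploidy and gender. Segments are stored as a
#' `data.table` with columns `chrom`, `start`, `end`, `total_cn`, `minor_cn`
#' (1-based inclusive coordinates; `minor_cn` may be `NA` for tumor-only
#' input, which is distinct from 0).
#'
#' @param sample_id sample identifier.
#' @param segments data.frame/data.table with columns `chrom`, `start`,
#'   `end`, `total_cn` and optionally `minor_cn`.
#' @param purity tumor cell fraction in (0, 1].
#' @param ploidy average tumor genome copy number, > 0.
#' @param gender `"XX"`, `"XY"` or `"unknown"`.
#' @return object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, segments, purity = 1, ploidy = 2,
                           gender = c("unknown", "XX", "XY")) {
  gender <- match.arg(gender)
  seg <- as.data.table(segments)
  if (!"minor_cn" %in% names(seg)) seg[, minor_cn := NA_integer_]
  req <- c("chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(seg))
  if (length(miss)) stopf("segments lack column(s): %s", paste(miss, collapse = ", "))
  seg <- seg[, req, with = FALSE]
  seg[, chrom := normalize_chrom(chrom)]
  seg[, `:=`(start = as.numeric(start), end = as.numeric(end),
             total_cn = as.integer(total_cn), minor_cn = as.integer(minor_cn))]
  setorder(seg, start)
  seg <- seg[order(chrom_rank(chrom), start)]
  obj <- structure(list(sample_id = as.character(sample_id), gender = gender,
                        purity = as.numeric(purity), ploidy = as.numeric(ploidy),
                        segments = seg[]),
                   class = "sample_profile")
  validate_profile(obj)
}

validate_profile <- function(p) {
  check_fraction(p$purity, sprintf("purity of %s", p$sample_id), lo_open = TRUE)
  if (!is.finite(p$ploidy) || p$ploidy <= 0)
    stopf("ploidy of %s must be > 0", p$sample_id)
  seg <- p$segments
  if (nrow(seg)) {
    bad <- seg[start > end]
    if (nrow(bad))
      stopf("sample %s: segment %s:%d-%d has end < start",
            p$sample_id, bad$chrom[1], as.integer(bad$start[1]), as.integer(bad$end[1]))
    if (any(seg$total_cn < 0, na.rm = TRUE))
      stopf("sample %s: negative total_cn", p$sample_id)
    bad <- seg[!is.na(minor_cn) & (minor_cn < 0 | minor_cn > total_cn)]
    if (nrow(bad))
      stopf("sample %s: minor_cn outside [0, total_cn] at %s:%d",
            p$sample_id, bad$chrom[1], as.integer(bad$start[1]))
    ov <- seg[, .(ov = any(start[-1] <= head(end, -1))), by = chrom][ov == TRUE]
    if (nrow(ov))
      stopf("sample %s: overlapping segments on chromosome %s",
            p$sample_id, ov$chrom[1])
  }
  p
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s: %d segments, purity %.2f, ploidy %.2f, %s\n",
              x$sample_id, nrow(x$segments), x$purity, x$ploidy, x$gender))
  invisible(x)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  dt <- tryCatch(fread(path, sep = "\t", header = TRUE, na.strings = c("NA", "")),
                 error = function(e) stopf("failed to parse %s (%s): %s",
                                           what, path, conditionMessage(e)))
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stopf("%s (%s) lacks required column(s): %s", what, path,
          paste(miss, collapse = ", "))
  dt
}

# Error if any value in `cols` fails as.numeric; reports the first offending
# data line (1-based, header = line 1).
coerce_numeric_cols <- function(dt, cols, path) {
  for (cl in cols) {
    v <- dt[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad))
      stopf("%s: non-numeric value '%s' in column '%s' at line %d",
            path, v[bad[1]], cl, bad[1] + 1L)
    set(dt, j = cl, value = num)
  }
  dt
}

#' Read allele-specific copy number segment profiles
#'
#' Parses a segment table into a list of [sample_profile()] objects. Two
#' dialects are supported:
#' \describe{
#'   \item{`ascat_tsv`}{columns `sample`, `chrom` (or `chromosome`), `start`,
#'     `end`, `total_cn`, `minor_cn`, and optionally `purity`, `ploidy`,
#'     `gender` as companion columns.}
#'   \item{`seg`}{like `ascat_tsv` but without a minor-allele column;
#'     `minor_cn` is recorded as missing (`NA`), which downstream code
#'     treats as "unavailable", not as 0.}
#' }
#' Purity/ploidy/gender may alternatively come from a sidecar TSV
#' (`sample`, `purity`, `ploidy`, `gender`); companion columns win. Samples
#' without either default to purity 1, ploidy 2, gender unknown.
#'
#' @param path segment TSV path.
#' @param dialect `"ascat_tsv"` or `"seg"`.
#' @param sidecar optional path of a per-sample purity/ploidy TSV.
#' @return named list of `sample_profile` objects.
#' @export
read_segments <- function(path, dialect = c("ascat_tsv", "seg"), sidecar = NULL) {
  dialect <- match.arg(dialect)
  req <- c("sample", "start", "end", "total_cn")
  if (dialect == "ascat_tsv") req <- c(req, "minor_cn")
  dt <- read_tsv_checked(path, character(), "segment table")
  if ("chromosome" %in% names(dt)) setnames(dt, "chromosome", "chrom")
  miss <- setdiff(c(req, "chrom"), names(dt))
  if (length(miss))
    stopf("segment table (%s) lacks required column(s): %s", path,
          paste(miss, collapse = ", "))
  numcols <- intersect(c("start", "end", "total_cn", "minor_cn", "purity", "ploidy"),
                       names(dt))
  coerce_numeric_cols(dt, numcols, path)
  bad <- which(dt$end < dt$start)
  if (length(bad))
    stopf("%s: end < start at line %d (%s:%d-%d)", path, bad[1] + 1L,
          dt$chrom[bad[1]], as.integer(dt$start[bad[1]]), as.integer(dt$end[bad[1]]))
  if (dialect == "seg" && !"minor_cn" %in% names(dt)) dt[, minor_cn := NA_real_]

  meta <- NULL
  if (!is.null(sidecar)) {
    meta <- read_tsv_checked(sidecar, "sample", "sidecar table")
    setkey(meta, sample)
  }
  field <- function(sub, m, col, default) {
    if (col %in% names(sub)) sub[[col]][1]
    else if (!is.null(m) && col %in% names(m) && !is.na(m[[col]][1])) m[[col]][1]
    else default
  }
  profs <- lapply(split(dt, by = "sample"), function(sub) {
    m <- if (!is.null(meta)) meta[J(sub$sample[1])] else NULL
    g <- as.character(field(sub, m, "gender", "unknown"))
    if (is.na(g) || !g %in% c("XX", "XY")) g <- "unknown"
    sample_profile(sub$sample[1],
                   sub[, .(chrom, start, end, total_cn, minor_cn)],
                   purity = field(sub, m, "purity", 1),
                   ploidy = field(sub, m, "ploidy", 2),
                   gender = g)
  })
  profs[order(names(profs))]
}

#' Read a gene model from BED
#'
#' BED3+ with a name column (and optional strand in column 6). BED 0-based
#' half-open coordinates are converted to the package's 1-based inclusive
#' convention (`start_internal = start_bed + 1`, `end_internal = end_bed`).
#'
#' @param path BED file path (tab-separated, no header).
#' @return data.table with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (carried, unused).
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stopf("gene BED not found: %s", path)
  dt <- if (file.size(path) == 0) data.table()
        else fread(path, sep = "\t", header = FALSE, fill = TRUE)
  if (!nrow(dt))
    return(data.table(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character()))
  if (ncol(dt) < 4) stopf("%s: BED needs >= 4 columns (chrom,start,end,name)", path)
  out <- data.table(gene_id = as.character(dt[[4]]),
                    chrom = normalize_chrom(dt[[1]]),
                    start = as.numeric(dt[[2]]) + 1,
                    end = as.numeric(dt[[3]]),
                    strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".")
  out[!strand %in% c("+", "-"), strand := "."]
  if (anyNA(out$gene_id) || any(out$gene_id == ""))
    stopf("%s: missing gene name in BED column 4", path)
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup)) stopf("%s: duplicate gene_id '%s'", path, dup[1])
  if (any(out$start > out$end)) stopf("%s: zero/negative-width BED interval", path)
  out[]
}

#' Read a per-gene amplicon-frequency prior table
#'
#' Five tab-separated columns: `gene_id`, `freq_Circular`, `freq_BFB`,
#' `freq_HR`, `freq_Linear` — the frequency with which each gene was seen on
#' circular (ecDNA), breakage-fusion-bridge, heavily-rearranged, or linear
#' amplicons in a reference amplicon catalog. Lookups of genes absent from
#' the table yield 0 for all four (documented default; see [prior_lookup()]).
#'
#' @param path prior TSV path.
#' @return data.table of class `amplicon_priors`, keyed by `gene_id`.
#' @export
read_priors <- function(path) {
  freq_cols <- c("freq_Circular", "freq_BFB", "freq_HR", "freq_Linear")
  dt <- read_tsv_checked(path, c("gene_id", freq_cols), "prior table")
  coerce_numeric_cols(dt, freq_cols, path)
  for (cl in freq_cols) check_fraction(dt[[cl]], sprintf("%s in %s", cl, path))
  dt <- dt[, c("gene_id", freq_cols), with = FALSE]
  dt[, gene_id := as.character(gene_id)]
  setkey(dt, gene_id)
  setattr(dt, "class", c("amplicon_priors", class(dt)))
  dt[]
}

#' Look up amplicon-frequency priors for a set of genes
#'
#' @param priors table from [read_priors()] (or compatible data.table).
#' @param gene_ids character vector.
#' @return data.table with one row per requested gene; genes absent from the
#'   table get all four frequencies set to 0.
#' @export
prior_lookup <- function(priors, gene_ids) {
  freq_cols <- c("freq_Circular", "freq_BFB", "freq_HR", "freq_Linear")
  pri <- as.data.table(priors)[, c("gene_id", freq_cols), with = FALSE]
  out <- pri[J(as.character(gene_ids)), on = "gene_id"]
  for (cl in freq_cols) set(out, which(is.na(out[[cl]])), cl, 0)
  out[]
}

CIRCLE_MAP_COLS <- c("chrom", "start", "end", "discordant_reads", "split_reads",
                     "circle_score", "mean_coverage", "coverage_sd",
                     "coverage_continuity")

#' Read Circle-Map Realign output records
#'
#' Expects the nine Circle-Map Realign columns in order: chrom, start, end,
#' discordant reads, split reads, circle score, mean coverage, coverage SD,
#' coverage continuity. A header row is optional.
#'
#' @param path BED-like TSV path.
#' @return data.table of typed records (coordinates as in the file,
#'   `end > start` enforced).
#' @export
read_circle_map <- function(path) {
  if (!file.exists(path)) stopf("Circle-Map file not found: %s", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) && suppressWarnings(is.na(as.numeric(first[2])))
  dt <- fread(path, sep = "\t", header = has_header, fill = TRUE)
  if (!nrow(dt)) stopf("%s: empty Circle-Map table", path)
  if (ncol(dt) < length(CIRCLE_MAP_COLS))
    stopf("%s: expected %d Circle-Map columns, found %d", path,
          length(CIRCLE_MAP_COLS), ncol(dt))
  dt <- dt[, seq_along(CIRCLE_MAP_COLS), with = FALSE]
  setnames(dt, CIRCLE_MAP_COLS)
  coerce_numeric_cols(dt, CIRCLE_MAP_COLS[-1], path)
  dt[, chrom := normalize_chrom(chrom)]
  if (any(dt$end <= dt$start)) stopf("%s: record with end <= start", path)
  if (any(dt$discordant_reads < 0 | dt$split_reads < 0))
    stopf("%s: negative read count", path)
  check_fraction(dt$coverage_continuity, "coverage_continuity")
  dt[]
}

#' Write gene- and sample-level focal amplification calls
#'
#' Emits a single tab-separated file with metadata comment lines (`#key=value`
#' recording the typing parameters) followed by one combined table with a
#' `level` column (`gene` rows carry probability/copy number, `sample` rows
#' carry the class and comma-separated cargo genes). [read_calls()] restores
#' both tables and the metadata.
#'
#' @param calls list with elements `genes` and `samples` as produced by
#'   [call_genes()] / [call_sample()], and optionally `params`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  genes <- as.data.table(calls$genes)
  samples <- as.data.table(calls$samples)
  params <- calls$params %||% list()
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("#%s=%s", k, format(params[[k]], digits = 15)), con)
  g <- if (nrow(genes)) {
    data.table(level = "gene", sample_id = genes$sample_id, id = genes$gene_id,
               klass = genes$klass,
               probability = format(genes$probability, digits = 15),
               total_cn = genes$total_cn, ploidy = genes$ploidy, cargo_genes = "")
  } else NULL
  s <- if (nrow(samples)) {
    data.table(level = "sample", sample_id = samples$sample_id, id = samples$sample_id,
               klass = samples$klass, probability = "", total_cn = NA_integer_,
               ploidy = NA_real_,
               cargo_genes = vapply(samples$cargo_genes, paste, "", collapse = ","))
  } else NULL
  out <- rbind(g, s)
  if (is.null(out))
    out <- data.table(level = character(), sample_id = character(), id = character(),
                      klass = character(), probability = character(),
                      total_cn = integer(), ploidy = numeric(), cargo_genes = character())
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, function(x) {
      x <- as.character(x); x[is.na(x)] <- "NA"; x
    }), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a call file written by [write_calls()]
#'
#' @param path call file path.
#' @return list with `genes`, `samples` (data.tables) and `params` (named
#'   list of metadata values).
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stopf("call file not found: %s", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  params <- list()
  for (m in meta) {
    kv <- strsplit(sub("^#", "", m), "=", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(kv[2]))
    params[[kv[1]]] <- if (is.na(v)) kv[2] else v
  }
  body <- lines[!grepl("^#", lines)]
  dt <- if (length(body) > 1)
    fread(text = body, sep = "\t", header = TRUE, colClasses = list(character = "cargo_genes"))
  else fread(text = body[1], sep = "\t", header = TRUE)
  genes <- dt[level == "gene",
              .(sample_id, gene_id = id, klass,
                probability = as.numeric(probability),
                total_cn = as.integer(total_cn), ploidy = as.numeric(ploidy))]
  samples <- dt[level == "sample",
                .(sample_id, klass,
                  cargo_genes = lapply(cargo_genes, function(x)
                    if (is.na(x) || x == "") character() else strsplit(x, ",")[[1]]))]
  list(genes = genes, samples = samples, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
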