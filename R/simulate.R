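# Synthetic-cohort simulator. Generates allele-specific copy number profiles
# with planted circular (ecDNA) and noncircular focal amplicons, arm-level
# aneuploidy, LOH tracts, purity/ploidy variation, and copy-number-coupled
# expression with an ecDNA-specific boost — plus complete ground truth, so
# the whole pipeline is testable without restricted tumor data. Default
# rates put the gene-level cargo fraction in the few-per-thousand regime
# that the classifier is designed for.

#' Simulation configuration
#'
#' The genome template is a scaled-down diploid genome: `n_chrom`
#' equally sized chromosomes split into p/q arms, with `n_genes` genes
#' placed at regular intervals. Planted event characteristics:
#' \itemize{
#'   \item circular (ecDNA) amplicons: copy number uniform on
#'     \[`cn_circular_min`, `cn_circular_max`\] (floor raised to the sample's
#'     focal-amplification threshold so every planted cargo gene is focally
#'     amplified), covering a run of `1 + Pois(genes_per_circular - 1)` genes;
#'   \item noncircular amplicons: copy number uniform on
#'     \[`cn_noncircular_min`, `cn_noncircular_max`\] (same floor rule);
#'   \item arm-level gains/losses at `arm_gain_rate`/`arm_loss_rate` per arm,
#'     LOH tracts at `loh_rate` per arm;
#'   \item purity uniform on (0.2, 1\]; ploidy 2/3/4 with probabilities
#'     `ploidy_probs` plus Gaussian jitter;
#'   \item expression `TPM = a*CN + b*cargo + type_offset + d*purity + noise`,
#'     truncated at 0.
#' }
#'
#' @param n_samples cohort size.
#' @param n_chrom,chrom_length,centromere genome template geometry (bp).
#' @param n_genes catalog size; `gene_length` bp each.
#' @param rate_circular_sample,rate_noncircular_sample per-sample event
#'   probabilities.
#' @param events_per_sample mean extra events per event-bearing sample
#'   (`1 + Pois(events_per_sample - 1)` events are planted).
#' @param genes_per_circular,genes_per_noncircular mean genes per event.
#' @param cn_circular_min,cn_circular_max,cn_noncircular_min,cn_noncircular_max
#'   integer copy-number ranges of planted amplicons.
#' @param arm_gain_rate,arm_loss_rate,loh_rate per-arm event rates.
#' @param purity_min lower purity bound.
#' @param ploidy_levels,ploidy_probs,ploidy_jitter_sd ploidy distribution.
#' @param expr_a,expr_b,expr_d,expr_noise_sd,cancer_type_offsets expression
#'   model parameters (slope per copy, ecDNA boost, purity slope, noise SD,
#'   named per-type intercept offsets).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200L,
                       n_chrom = 8L, chrom_length = 120e6, centromere = 45e6,
                       n_genes = 1000L, gene_length = 5e4,
                       rate_circular_sample = 0.25,
                       rate_noncircular_sample = 0.25,
                       events_per_sample = 2,
                       genes_per_circular = 6, genes_per_noncircular = 4,
                       cn_circular_min = 8L, cn_circular_max = 100L,
                       cn_noncircular_min = 5L, cn_noncircular_max = 12L,
                       arm_gain_rate = 0.1, arm_loss_rate = 0.1, loh_rate = 0.15,
                       purity_min = 0.2,
                       ploidy_levels = c(2, 3, 4),
                       ploidy_probs = c(0.7, 0.2, 0.1),
                       ploidy_jitter_sd = 0.05,
                       expr_a = 5, expr_b = 50, expr_d = 10, expr_noise_sd = 10,
                       cancer_type_offsets = c(typeA = 0, typeB = 20, typeC = 40),
                       seed = 1L) {
  stopifnot(n_samples >= 1, n_chrom >= 1, n_genes >= n_chrom,
            centromere < chrom_length,
            all(c(rate_circular_sample, rate_noncircular_sample,
                  arm_gain_rate, arm_loss_rate, loh_rate) >= 0),
            all(c(rate_circular_sample, rate_noncircular_sample,
                  arm_gain_rate, arm_loss_rate, loh_rate) <= 1))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Genome template of a simulation configuration
#'
#' @param config a [sim_config()].
#' @return list with `genes` (annotation table), `arms` (arm table usable by
#'   [compute_aneuploidy_score()]) and `chrom_lengths` (named vector).
#' @export
sim_genome <- function(config) {
  chroms <- as.character(seq_len(config$n_chrom))
  arms <- rbindlist(lapply(chroms, function(ch) data.table(
    chrom = ch, arm = paste0(ch, c("p", "q")),
    start = c(1, config$centromere + 1),
    end = c(config$centromere, config$chrom_length),
    excluded = FALSE)))
  per <- ceiling(config$n_genes / config$n_chrom)
  genes <- rbindlist(lapply(seq_along(chroms), function(i) {
    n_here <- min(per, config$n_genes - (i - 1) * per)
    if (n_here <= 0) return(NULL)
    gap <- floor((config$chrom_length - config$gene_length - 1) / n_here)
    starts <- 1 + gap * (seq_len(n_here) - 1) + floor(gap / 2)
    data.table(gene_id = sprintf("g%s_%03d", chroms[i], seq_len(n_here)),
               chrom = chroms[i], start = starts,
               end = starts + config$gene_length - 1, strand = ".")
  }))
  list(genes = genes, arms = arms,
       chrom_lengths = setNames(rep(config$chrom_length, config$n_chrom), chroms))
}

# Piecewise-constant CN track for one chromosome: later layers override
# earlier ones. layers: data.table(start, end, total_cn, minor_cn).
flatten_layers <- function(layers, chrom_len) {
  bp <- sort(unique(c(1, chrom_len + 1, layers$start, layers$end + 1)))
  bp <- bp[bp >= 1 & bp <= chrom_len + 1]
  out <- data.table(start = head(bp, -1), end = tail(bp, -1) - 1,
                    total_cn = NA_integer_, minor_cn = NA_integer_)
  for (i in seq_len(nrow(layers))) {
    idx <- out$start >= layers$start[i] & out$end <= layers$end[i]
    out[idx, `:=`(total_cn = layers$total_cn[i], minor_cn = layers$minor_cn[i])]
  }
  # merge adjacent runs with identical state
  grp <- cumsum(c(TRUE, out$total_cn[-1] != head(out$total_cn, -1) |
                    xor(is.na(out$minor_cn[-1]), is.na(head(out$minor_cn, -1))) |
                    fcoalesce(out$minor_cn[-1] != head(out$minor_cn, -1), FALSE)))
  out[, g := grp]
  out <- out[, .(start = min(start), end = max(end),
                 total_cn = total_cn[1], minor_cn = minor_cn[1]), by = g][, -"g"]
  out[]
}

#' Simulate one tumor profile with ground truth
#'
#' Baseline copy number is the sample's rounded ploidy genome-wide; arm
#' gains/losses, LOH tracts and planted focal amplicons override it locally.
#' Deterministic given `config$seed + sample_index`.
#'
#' @param config a [sim_config()].
#' @param sample_index integer index (1-based) within the cohort.
#' @param genome optional precomputed [sim_genome()] (recomputed if NULL).
#' @return list `profile` ([sample_profile()]), `truth` (per-gene
#'   data.table: `sample_id`, `gene_id`, `klass`, `is_cargo`, `planted_cn`),
#'   `sample_klass`, `purity`, `ploidy`, `cancer_type`.
#' @export
simulate_profile <- function(config, sample_index, genome = NULL) {
  genome <- genome %||% sim_genome(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + sample_index)
  sid <- sprintf("S%04d", sample_index)

  purity <- runif(1, config$purity_min, 1)
  ploidy <- config$ploidy_levels[sample.int(length(config$ploidy_levels), 1,
                                            prob = config$ploidy_probs)] +
    rnorm(1, 0, config$ploidy_jitter_sd)
  base_cn <- max(1L, as.integer(round_half_away(ploidy)))
  base_minor <- as.integer(floor(base_cn / 2))
  cancer_type <- sample(names(config$cancer_type_offsets), 1)

  genes <- genome$genes
  arms <- genome$arms
  amp_floor <- function(lo) max(lo, as.integer(ceiling(2.25 * ploidy)))

  # per-chromosome layer stacks, in override order
  layers <- lapply(seq_len(config$n_chrom), function(i)
    data.table(start = 1, end = config$chrom_length,
               total_cn = base_cn, minor_cn = base_minor))
  names(layers) <- as.character(seq_len(config$n_chrom))

  for (i in seq_len(nrow(arms))) {
    ch <- arms$chrom[i]
    delta <- 0L
    if (runif(1) < config$arm_gain_rate) delta <- delta + 1L
    if (runif(1) < config$arm_loss_rate) delta <- delta - 1L
    if (delta != 0L) {
      cn <- max(0L, base_cn + delta)
      layers[[ch]] <- rbind(layers[[ch]],
                            data.table(start = arms$start[i], end = arms$end[i],
                                       total_cn = cn,
                                       minor_cn = min(base_minor, cn)))
    }
    if (runif(1) < config$loh_rate) {
      w <- arms$end[i] - arms$start[i] + 1
      t_start <- arms$start[i] + floor(runif(1, 0, 0.5) * w)
      t_end <- t_start + floor(runif(1, 0.2, 0.5) * w)
      t_end <- min(t_end, arms$end[i])
      cur <- max(1L, base_cn)
      layers[[ch]] <- rbind(layers[[ch]],
                            data.table(start = t_start, end = t_end,
                                       total_cn = cur, minor_cn = 0L))
    }
  }

  truth <- data.table(sample_id = sid, gene_id = genes$gene_id,
                      klass = factor("nofocal", levels = FOCAL_CLASSES),
                      is_cargo = FALSE, planted_cn = NA_integer_)
  plant <- function(event_klass) {
    n_ev <- 1L + rpois(1, config$events_per_sample - 1)
    for (e in seq_len(n_ev)) {
      mean_genes <- if (event_klass == "circular") config$genes_per_circular
                    else config$genes_per_noncircular
      n_g <- 1L + rpois(1, mean_genes - 1)
      ch <- sample(as.character(seq_len(config$n_chrom)), 1)
      cg <- genes[chrom == ch]
      if (!nrow(cg)) next
      i0 <- sample(nrow(cg), 1)
      idx <- i0:min(nrow(cg), i0 + n_g - 1)
      cn <- if (event_klass == "circular")
        sample(amp_floor(config$cn_circular_min):config$cn_circular_max, 1)
      else {
        lo <- amp_floor(config$cn_noncircular_min)
        hi <- max(lo, config$cn_noncircular_max)
        sample(lo:hi, 1)
      }
      region <- c(min(cg$start[idx]) - 1e4, max(cg$end[idx]) + 1e4)
      layers[[ch]] <<- rbind(layers[[ch]],
                             data.table(start = max(1, region[1]),
                                        end = min(config$chrom_length, region[2]),
                                        total_cn = as.integer(cn), minor_cn = 1L))
      sel <- truth$gene_id %in% cg$gene_id[idx]
      # circular takes precedence over an earlier noncircular plant
      upgrade <- sel & match(event_klass, FOCAL_CLASSES) <
        match(as.character(truth$klass), FOCAL_CLASSES)
      new_cargo <- event_klass == "circular"
      planted <- as.integer(cn)
      truth[upgrade, `:=`(klass = factor(event_klass, levels = FOCAL_CLASSES),
                          is_cargo = new_cargo,
                          planted_cn = planted)]
    }
  }
  has_circ <- runif(1) < config$rate_circular_sample
  has_nonc <- runif(1) < config$rate_noncircular_sample
  if (has_nonc) plant("noncircular")
  if (has_circ) plant("circular")

  seg <- rbindlist(lapply(names(layers), function(ch)
    cbind(chrom = ch, flatten_layers(layers[[ch]], config$chrom_length))))
  profile <- sample_profile(sid, seg, purity = purity, ploidy = ploidy,
                            gender = "unknown")
  sample_klass <- if (any(truth$klass == "circular")) "circular"
                  else if (any(truth$klass == "noncircular")) "noncircular"
                  else "nofocal"
  list(profile = profile, truth = truth,
       sample_klass = factor(sample_klass, levels = FOCAL_CLASSES),
       purity = purity, ploidy = ploidy, cancer_type = cancer_type)
}

#' Simulate a cohort with ground truth and coupled expression
#'
#' Runs [simulate_profile()] for every sample, derives the amplicon-frequency
#' prior table from the planted catalog itself (per-gene frequency of each
#' planted class across the cohort; noncircular plants feed the BFB prior),
#' and generates expression as
#' `TPM = a*CN + b*cargo + type_offset + d*purity + N(0, sd)`, truncated at 0,
#' where CN is the gene-level collapsed copy number.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `profiles`, `truth_genes`,
#'   `truth_samples`, `expression`, `priors`, `genes`, `arms`,
#'   `chrom_lengths`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (config$n_samples < 1) stopf("n_samples must be >= 1")
  genome <- sim_genome(config)
  sims <- lapply(seq_len(config$n_samples), function(i)
    simulate_profile(config, i, genome))
  profiles <- lapply(sims, `[[`, "profile")
  names(profiles) <- vapply(profiles, `[[`, "", "sample_id")
  truth_genes <- rbindlist(lapply(sims, `[[`, "truth"))
  truth_samples <- data.table(
    sample_id = names(profiles),
    klass = factor(vapply(sims, function(s) as.character(s$sample_klass), ""),
                   levels = FOCAL_CLASSES),
    purity = vapply(sims, `[[`, 0, "purity"),
    ploidy = vapply(sims, `[[`, 0, "ploidy"),
    cancer_type = vapply(sims, `[[`, "", "cancer_type"))

  pri <- truth_genes[, .(
    freq_Circular = mean(klass == "circular"),
    freq_BFB = mean(klass == "noncircular"),
    freq_HR = 0, freq_Linear = 0), by = gene_id]
  setkey(pri, gene_id)
  setattr(pri, "class", c("amplicon_priors", class(pri)))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + config$n_samples + 1L)
  expr <- rbindlist(lapply(sims, function(s) {
    cn <- collapse_to_gene_cn(s$profile, genome$genes)
    tpm <- config$expr_a * fcoalesce(as.numeric(cn$total_cn), 2) +
      config$expr_b * as.numeric(s$truth$is_cargo) +
      config$cancer_type_offsets[[s$cancer_type]] +
      config$expr_d * s$purity +
      rnorm(nrow(cn), 0, config$expr_noise_sd)
    data.table(sample_id = s$profile$sample_id, gene_id = cn$gene_id,
               TPM = pmax(0, tpm), CN = cn$total_cn,
               circular = as.numeric(s$truth$is_cargo),
               cancer_type = s$cancer_type, purity = s$purity)
  }))
  structure(list(profiles = profiles, truth_genes = truth_genes,
                 truth_samples = truth_samples, expression = expr,
                 priors = pri[], genes = genome$genes, arms = genome$arms,
                 chrom_lengths = genome$chrom_lengths, config = config),
            class = "sim_cohort")
}

#' Labeled feature table of a simulated cohort
#'
#' Convenience wrapper: [build_feature_matrix()] on the cohort's own genome
#' template and truth-derived priors, joined with the cargo-gene truth label.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return feature data.table with a `label` column.
#' @export
sim_feature_table <- function(cohort) {
  fm <- build_feature_matrix(cohort$profiles, cohort$genes, cohort$priors,
                             arms = cohort$arms)
  lab <- cohort$truth_genes[, .(sample_id, gene_id, label = as.numeric(is_cargo))]
  merge(fm, lab, by = c("sample_id", "gene_id"), sort = FALSE)
}

#' Export a simulated cohort as plain-text fixtures
#'
#' Writes `segments.tsv` (ASCAT-style with companion purity/ploidy columns),
#' `genes.bed`, `priors.tsv`, `expression.tsv`, `truth_genes.tsv`,
#' `truth_samples.tsv` and `arms.tsv`, all re-readable by the genome-io
#' readers.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
export_fixtures <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory %s", dir)
  }
  paths <- c(segments = file.path(dir, "segments.tsv"),
             genes = file.path(dir, "genes.bed"),
             priors = file.path(dir, "priors.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_samples = file.path(dir, "truth_samples.tsv"),
             arms = file.path(dir, "arms.tsv"))
  segs <- rbindlist(lapply(cohort$profiles, function(p)
    cbind(data.table(sample = p$sample_id), p$segments,
          purity = p$purity, ploidy = p$ploidy, gender = p$gender)))
  fwrite(segs, paths["segments"], sep = "\t")
  bed <- cohort$genes[, .(chrom, start = format(start - 1, scientific = FALSE, trim = TRUE),
                          end = format(end, scientific = FALSE, trim = TRUE),
                          gene_id, score = 0, strand)]
  fwrite(bed, paths["genes"], sep = "\t", col.names = FALSE)
  fwrite(as.data.table(cohort$priors), paths["priors"], sep = "\t")
  fwrite(cohort$expression, paths["expression"], sep = "\t")
  fwrite(cohort$truth_genes, paths["truth_genes"], sep = "\t")
  fwrite(cohort$truth_samples, paths["truth_samples"], sep = "\t")
  arms_out <- copy(cohort$arms)[, excluded := as.integer(excluded)]
  fwrite(arms_out, paths["arms"], sep = "\t")
  invisible(paths)
}
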