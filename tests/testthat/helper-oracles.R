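# Independent brute-force oracles. These deliberately share no code with the
# package implementations: metrics by explicit threshold enumeration /
# pairwise counting, genome summaries by per-basepair scans, gene collapsing
# by exhaustive overlap enumeration.

ap_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_tp <- 0
  ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    ap <- ap + (tp - prev_tp) * prec
    prev_tp <- tp
  }
  ap / sum(labels == 1)
}

auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# per-bp scan oracles; profiles must be small (<= ~1 Mb coordinates)
bp_track <- function(seg) {
  # returns list(total, minor) vectors indexed by bp over covered positions
  n <- max(seg$end)
  total <- rep(NA_integer_, n)
  minor <- rep(NA_integer_, n)
  for (i in seq_len(nrow(seg))) {
    idx <- seg$start[i]:seg$end[i]
    total[idx] <- seg$total_cn[i]
    minor[idx] <- seg$minor_cn[i]
  }
  list(total = total, minor = minor)
}

ploh_oracle <- function(profile) {
  seg <- profile$segments[chrom %in% as.character(1:22) & !is.na(minor_cn)]
  num <- 0; den <- 0
  for (ch in unique(seg$chrom)) {
    tr <- bp_track(seg[chrom == ch])
    covered <- !is.na(tr$total)
    den <- den + sum(covered)
    num <- num + sum(covered & tr$minor == 0 & tr$total >= 1, na.rm = TRUE)
  }
  num / den
}

burden_oracle <- function(profile) {
  base <- sign(profile$ploidy) * floor(abs(profile$ploidy) + 0.5)
  seg <- profile$segments[chrom %in% as.character(1:22)]
  num <- 0; den <- 0
  for (ch in unique(seg$chrom)) {
    tr <- bp_track(seg[chrom == ch])
    covered <- !is.na(tr$total)
    den <- den + sum(covered)
    num <- num + sum(covered & tr$total != base, na.rm = TRUE)
  }
  num / den
}

ascore_oracle <- function(profile, arms) {
  base <- sign(profile$ploidy) * floor(abs(profile$ploidy) + 0.5)
  arms <- arms[arms$excluded == FALSE & arms$chrom %in% as.character(1:22), ]
  seg <- profile$segments[chrom %in% as.character(1:22)]
  score <- 0
  for (i in seq_len(nrow(arms))) {
    sub <- seg[chrom == arms$chrom[i]]
    if (!nrow(sub)) next
    cns <- c()
    for (j in seq_len(nrow(sub))) {
      lo <- max(sub$start[j], arms$start[i]); hi <- min(sub$end[j], arms$end[i])
      if (lo <= hi) cns <- c(cns, rep(sub$total_cn[j], hi - lo + 1))
    }
    if (!length(cns)) next
    m <- mean(cns)
    arm_cn <- sign(m) * floor(abs(m) + 0.5)
    if (arm_cn != base) score <- score + 1
  }
  score
}

collapse_oracle <- function(profile, genes) {
  seg <- profile$segments
  res <- data.table::data.table(gene_id = genes$gene_id,
                                total_cn = NA_integer_, minor_cn = NA_integer_)
  for (g in seq_len(nrow(genes))) {
    best_ov <- 0; best_cn <- -1L; best_minor <- NA_integer_
    for (s in seq_len(nrow(seg))) {
      if (seg$chrom[s] != genes$chrom[g]) next
      ov <- min(genes$end[g], seg$end[s]) - max(genes$start[g], seg$start[s]) + 1
      if (ov <= 0) next
      if (ov > best_ov || (ov == best_ov && seg$total_cn[s] > best_cn)) {
        best_ov <- ov; best_cn <- seg$total_cn[s]; best_minor <- seg$minor_cn[s]
      }
    }
    if (best_ov > 0)
      res[g, c("total_cn", "minor_cn") := .(best_cn, best_minor)]
  }
  res
}

# random small profile over 2 chromosomes, coordinates <= 1e6
random_small_profile <- function(seed, allow_na_minor = FALSE) {
  set.seed(seed)
  segs <- data.table::rbindlist(lapply(c("1", "2"), function(ch) {
    n <- sample(1:10, 1)
    bounds <- sort(sample(1:1e6, 2 * n))
    starts <- bounds[seq(1, 2 * n, by = 2)]
    ends <- bounds[seq(2, 2 * n, by = 2)]
    total <- sample(0:8, n, replace = TRUE)
    minor <- pmin(total, sample(0:3, n, replace = TRUE))
    if (allow_na_minor) minor[sample(n, 1)] <- NA_integer_
    data.table::data.table(chrom = ch, start = starts, end = ends,
                           total_cn = total, minor_cn = minor)
  }))
  sample_profile(sprintf("R%05d", seed), segs,
                 purity = runif(1, 0.3, 1),
                 ploidy = runif(1, 1.5, 4.5))
}

small_arm_table <- function() {
  data.table::data.table(
    chrom = c("1", "1", "2", "2"),
    arm = c("1p", "1q", "2p", "2q"),
    start = c(1, 400001, 1, 500001),
    end = c(400000, 1e6, 500000, 1e6),
    excluded = FALSE)
}

random_genes <- function(seed, n = 8) {
  set.seed(seed + 5000)
  starts <- sample(1:9e5, n)
  data.table::data.table(gene_id = sprintf("G%02d", seq_len(n)),
                         chrom = sample(c("1", "2"), n, replace = TRUE),
                         start = starts,
                         end = starts + sample(1e3:5e4, n),
                         strand = ".")
}
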