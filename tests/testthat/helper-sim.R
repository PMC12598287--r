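# Shared fixture builders: everything is generated in code at test time.

# quick single-sample callset on evenly spaced sites of one chromosome
make_callset <- function(dosage, spacing = 1000, chrom = "1", maf = 0.25,
                         gp = NULL, sample_id = "s1", start = 0) {
  n <- length(dosage)
  sites <- new_sites(rep(chrom, n), start + (0:(n - 1)) * spacing,
                     rep("A", n), rep("C", n), rep(maf, n))
  new_callset(sample_id, sites, dosage, gp)
}

# small panel + truth bundle used by several modules
small_panel <- function(n_sites = 2000, chrom_lengths = c("1" = 1e7),
                        n_haplotypes = 40, seed = 42) {
  simulate_panel(panel_config(
    n_founders = 10, n_haplotypes = n_haplotypes, n_sites = n_sites,
    chrom_lengths = chrom_lengths, seed = seed))
}

# independent brute-force window-scan ROH oracle: literal nested loops
brute_windowscan <- function(d, pos, params) {
  n <- length(d); w <- params$window_snp
  segs <- list()
  if (n >= w) {
    hit <- logical(n - w + 1)
    for (i in seq_len(n - w + 1)) {
      win <- d[i:(i + w - 1)]
      hit[i] <- sum(win == 1, na.rm = TRUE) <= params$window_het &&
        sum(is.na(win)) <= params$window_missing
    }
    pass <- logical(n)
    for (j in seq_len(n)) {
      ws <- max(1, j - w + 1):min(j, n - w + 1)
      pass[j] <- mean(hit[ws]) >= params$window_threshold
    }
    j <- 1
    while (j <= n) {
      if (!pass[j]) { j <- j + 1; next }
      k <- j
      while (k < n && pass[k + 1]) k <- k + 1
      a <- j; b <- k
      while (a <= b && (is.na(d[a]) || d[a] == 1)) a <- a + 1
      while (b >= a && (is.na(d[b]) || d[b] == 1)) b <- b - 1
      if (a <= b) {
        idx <- a:b
        brks <- which(diff(pos[idx]) > params$max_gap_kb * 1000)
        st <- c(1, brks + 1); en <- c(brks, length(idx))
        for (q in seq_along(st)) {
          pi <- idx[st[q]:en[q]]
          len <- pos[pi[length(pi)]] - pos[pi[1]] + 1
          if (length(pi) >= params$min_snp && len >= params$min_kb * 1000 &&
              (len / 1000) / length(pi) <= params$max_density_kb_per_snp)
            segs[[length(segs) + 1]] <- data.frame(
              start = pos[pi[1]], end = pos[pi[length(pi)]] + 1,
              n_snps = length(pi))
        }
      }
      j <- k + 1
    }
  }
  if (length(segs) == 0)
    data.frame(start = numeric(), end = numeric(), n_snps = integer())
  else do.call(rbind, segs)
}

# realized autozygous tract containing a planted segment: the planted
# coordinates extended to the boundaries of the maximal homozygous run
# (chance autozygosity abutting a planted tract is part of the same run,
# and no genotype-level caller can see the planted boundary inside it)
hom_run_bounds <- function(cs, start, end) {
  pos <- cs$sites$pos
  d <- cs$dosage
  het <- which(!is.na(d) & d == 1L)
  before <- het[pos[het] < start]
  after <- het[pos[het] >= end]
  lo_idx <- if (length(before)) max(before) + 1L else 1L
  hi_idx <- if (length(after)) min(after) - 1L else length(pos)
  c(pos[lo_idx], pos[hi_idx] + 1)
}

# exhaustive max-probability path over all 2^L state sequences
brute_best_path <- function(model) {
  n <- ncol(model$emit)
  M <- 2^n
  paths <- matrix(0L, M, n)
  for (t in seq_len(n)) paths[, t] <- bitwAnd(0:(M - 1), bitwShiftL(1L, t - 1L)) > 0
  paths <- paths + 1L  # 1 = AZ, 2 = HW
  lp <- log(model$init[paths[, 1]]) + log(model$emit)[cbind(paths[, 1], 1)]
  if (n > 1) for (t in 2:n) {
    from_az <- paths[, t - 1] == 1L
    to_az <- paths[, t] == 1L
    tp <- ifelse(from_az,
                 ifelse(to_az, 1 - model$p_ah[t - 1], model$p_ah[t - 1]),
                 ifelse(to_az, model$p_ha[t - 1], 1 - model$p_ha[t - 1]))
    lp <- lp + log(tp) + log(model$emit)[cbind(paths[, t], t)]
  }
  list(logp = max(lp), path = paths[which.max(lp), ])
}
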