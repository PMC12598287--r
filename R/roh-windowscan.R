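#' Parameters of the window-scan ROH caller
#'
#' The plink-style parameterization used for imputed ancient genomes:
#' 50-SNP scanning windows allowing at most 1 heterozygote and 5 missing
#' calls, a SNP passes when at least 5% of the windows covering it are
#' homozygous hits, and final runs must carry at least 200 SNPs over at
#' least 500 kb with at most 50 kb per SNP and no inter-SNP gap above
#' 100 kb.
#'
#' @param window_snp scanning-window size in SNPs.
#' @param window_het maximum heterozygous calls per hit window.
#' @param window_missing maximum missing calls per hit window.
#' @param window_threshold minimum hit fraction for a SNP to pass.
#' @param min_snp minimum SNPs per reported run.
#' @param min_kb minimum run length in kb.
#' @param max_density_kb_per_snp maximum kb per SNP within a run.
#' @param max_gap_kb maximum gap between adjacent run SNPs in kb.
#' @return A `windowscan_params` list.
#' @export
windowscan_params <- function(window_snp = 50, window_het = 1,
                              window_missing = 5, window_threshold = 0.05,
                              min_snp = 200, min_kb = 500,
                              max_density_kb_per_snp = 50,
                              max_gap_kb = 100) {
  stopifnot(window_snp > 0, window_het >= 0, window_het < window_snp,
            window_missing >= 0, window_threshold > 0, min_snp > 0,
            min_kb > 0, max_density_kb_per_snp > 0, max_gap_kb > 0)
  structure(as.list(environment()), class = "windowscan_params")
}

#' Window-scan ROH caller
#'
#' Calls runs of homozygosity by the sliding-window algorithm: (1) every
#' window of `window_snp` consecutive SNPs is a "hit" iff it contains at
#' most `window_het` heterozygous and at most `window_missing` missing
#' calls; (2) each SNP's hit fraction is the proportion of hits among the
#' windows containing it, and the SNP passes iff that fraction reaches
#' `window_threshold`; (3) candidate runs are maximal stretches of passing
#' SNPs, trimmed so both ends are non-missing homozygous calls; (4) runs are
#' split where adjacent SNPs are more than `max_gap_kb` apart; (5) runs are
#' reported if they carry `min_snp` SNPs, span `min_kb` kb, and have at most
#' `max_density_kb_per_snp` kb per SNP. Chromosomes with fewer than
#' `window_snp` SNPs yield no calls.
#'
#' @param callset single-sample [new_callset()].
#' @param params a [windowscan_params()].
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`
#'   (0-based half-open, first to last run SNP), `n_snps`, `length_bp`,
#'   `source = "windowscan"`.
#' @export
windowscan_roh <- function(callset, params = windowscan_params()) {
  stopifnot(inherits(params, "windowscan_params"))
  segs <- list()
  for (ch in unique(callset$sites$chrom)) {
    sel <- which(callset$sites$chrom == ch)
    d <- callset$dosage[sel]
    pos <- callset$sites$pos[sel]
    n <- length(d)
    w <- params$window_snp
    if (n < w) next
    het <- as.integer(!is.na(d) & d == 1L)
    mis <- as.integer(is.na(d))
    # hit indicator for windows starting at 1..n-w+1
    csh <- c(0, cumsum(het)); csm <- c(0, cumsum(mis))
    W <- n - w + 1
    starts <- seq_len(W)
    hit <- (csh[starts + w] - csh[starts]) <= params$window_het &
           (csm[starts + w] - csm[starts]) <= params$window_missing
    # SNP j is covered by window starts max(1, j-w+1) .. min(j, W)
    csum_hit <- c(0, cumsum(hit))
    jlo <- pmax(1L, seq_len(n) - w + 1L)
    jhi <- pmin(seq_len(n), W)
    n_cov <- jhi - jlo + 1L
    n_hit <- csum_hit[jhi + 1L] - csum_hit[jlo]
    pass <- (n_hit / n_cov) >= params$window_threshold
    # maximal runs of passing SNPs
    r <- rle(pass)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts_idx[k]; b <- ends_idx[k]
      # trim ends to non-missing homozygous calls
      while (a <= b && (is.na(d[a]) || d[a] == 1L)) a <- a + 1L
      while (b >= a && (is.na(d[b]) || d[b] == 1L)) b <- b - 1L
      if (a > b) next
      idx <- a:b
      # split at gaps > max_gap_kb
      gap_break <- which(diff(pos[idx]) > params$max_gap_kb * 1000)
      piece_end <- c(gap_break, length(idx))
      piece_start <- c(1, gap_break + 1)
      for (p in seq_along(piece_start)) {
        pi <- idx[piece_start[p]:piece_end[p]]
        n_snps <- length(pi)
        len_bp <- pos[pi[n_snps]] - pos[pi[1]] + 1
        if (n_snps >= params$min_snp &&
            len_bp >= params$min_kb * 1000 &&
            (len_bp / 1000) / n_snps <= params$max_density_kb_per_snp) {
          segs[[length(segs) + 1]] <- data.frame(
            sample = callset$sample_id, chrom = ch,
            start = pos[pi[1]], end = pos[pi[n_snps]] + 1,
            n_snps = n_snps, length_bp = len_bp,
            source = "windowscan", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
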