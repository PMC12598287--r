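#' Parameters of the HMM ROH caller
#'
#' A two-state hidden Markov model over called genotypes, in the style of
#' genotype-based autozygosity HMMs: states AZ (autozygous) and HW
#' (Hardy-Weinberg). With genotype error `e = 10^(-err_phred/10)`, emissions
#' are `P(het|AZ) = e` and `P(het|HW) = 2p(1-p)(1-e) + (1-2p(1-p))e` for
#' site ALT frequency `p` (defaulted to `af_default` where unknown).
#' Transition probabilities scale with the bp distance `d` between adjacent
#' sites, capped at 0.49: `P(HW->AZ) = min(t_hw2az * d, 0.49)` and
#' symmetrically for AZ->HW. Segments are Viterbi AZ runs; a per-segment
#' quality is derived from forward-backward posteriors.
#'
#' @param err_phred phred-scaled genotype error (default 30).
#' @param af_default ALT frequency used where none is supplied (default 0.4).
#' @param t_hw2az,t_az2hw transition rates per bp.
#' @param min_snp,min_qual,min_kb segment filters: at least `min_snp` SNPs,
#'   quality strictly greater than `min_qual`, length at least `min_kb` kb.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(err_phred = 30, af_default = 0.4,
                       t_hw2az = 6.7e-8, t_az2hw = 5e-9,
                       min_snp = 200, min_qual = 10, min_kb = 500) {
  stopifnot(err_phred > 0, af_default > 0, af_default < 1,
            t_hw2az > 0, t_az2hw > 0, min_snp > 0, min_kb > 0)
  structure(as.list(environment()), class = "hmm_params")
}

# emission and transition matrices for one chromosome's called sites
hmm_model <- function(pos, het, p, params) {
  e <- 10^(-params$err_phred / 10)
  phw_het <- 2 * p * (1 - p) * (1 - e) + (1 - 2 * p * (1 - p)) * e
  # rows: state (1 = AZ, 2 = HW); emission prob of the observed genotype
  emit <- rbind(ifelse(het, e, 1 - e),
                ifelse(het, phw_het, 1 - phw_het))
  d <- diff(pos)
  p_ha <- pmin(params$t_hw2az * d, 0.49)
  p_ah <- pmin(params$t_az2hw * d, 0.49)
  list(emit = emit, p_ha = p_ha, p_ah = p_ah, init = c(0.5, 0.5))
}

# Viterbi path (1 = AZ, 2 = HW) in log space
hmm_viterbi <- function(model) {
  n <- ncol(model$emit)
  le <- log(model$emit)
  v <- matrix(-Inf, 2, n)
  bk <- matrix(0L, 2, n)
  v[, 1] <- log(model$init) + le[, 1]
  for (t in seq_len(n)[-1]) {
    lt <- log(rbind(c(1 - model$p_ah[t - 1], model$p_ah[t - 1]),
                    c(model$p_ha[t - 1], 1 - model$p_ha[t - 1])))
    for (s in 1:2) {
      cand <- v[, t - 1] + lt[, s]
      bk[s, t] <- which.max(cand)
      v[s, t] <- max(cand) + le[s, t]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[, n])
  if (n > 1) for (t in (n - 1):1) path[t] <- bk[path[t + 1], t + 1]
  list(path = path, logp = max(v[, n]))
}

# scaled forward-backward; returns posterior P(AZ) per site
hmm_posterior <- function(model) {
  n <- ncol(model$emit)
  a <- matrix(0, 2, n); b <- matrix(0, 2, n); sc <- numeric(n)
  a[, 1] <- model$init * model$emit[, 1]
  sc[1] <- sum(a[, 1]); a[, 1] <- a[, 1] / sc[1]
  trans <- function(t) rbind(c(1 - model$p_ah[t], model$p_ah[t]),
                             c(model$p_ha[t], 1 - model$p_ha[t]))
  for (t in seq_len(n)[-1]) {
    a[, t] <- (t(trans(t - 1)) %*% a[, t - 1]) * model$emit[, t]
    sc[t] <- sum(a[, t]); a[, t] <- a[, t] / sc[t]
  }
  b[, n] <- 1
  if (n > 1) for (t in (n - 1):1) {
    b[, t] <- trans(t) %*% (model$emit[, t + 1] * b[, t + 1])
    b[, t] <- b[, t] / sc[t + 1]
  }
  post <- a * b
  post <- sweep(post, 2, colSums(post), "/")
  post[1, ]
}

#' HMM ROH caller
#'
#' Runs the two-state autozygosity HMM of [hmm_params()] over each
#' chromosome's non-missing calls, reports maximal Viterbi AZ runs, scores
#' each run with `quality = -10*log10(1 - median per-site AZ posterior)`,
#' and filters by `min_snp`, `min_qual` (strictly greater) and `min_kb`.
#'
#' @param callset single-sample [new_callset()].
#' @param site_freqs optional ALT-frequency vector aligned to the callset's
#'   sites; defaults to the sites' `alt_freq` column when present, else to
#'   `af_default` everywhere. `NA` entries fall back to `af_default`.
#' @param params an [hmm_params()].
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`,
#'   `n_snps`, `length_bp`, `source = "hmm"`, `quality`.
#' @export
hmm_roh <- function(callset, site_freqs = NULL, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  sites <- callset$sites
  if (is.null(site_freqs))
    site_freqs <- if ("alt_freq" %in% names(sites)) sites$alt_freq
                  else rep(NA_real_, nrow(sites))
  site_freqs[is.na(site_freqs)] <- params$af_default
  # clamp panel-boundary frequencies into the open interval
  site_freqs <- pmin(pmax(site_freqs, 1e-6), 1 - 1e-6)
  if (any(site_freqs <= 0 | site_freqs >= 1))
    stop("site frequencies must lie in (0, 1) after defaulting")
  segs <- list()
  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch & !is.na(callset$dosage))
    if (length(sel) < 2) next
    pos <- sites$pos[sel]
    het <- callset$dosage[sel] == 1L
    model <- hmm_model(pos, het, site_freqs[sel], params)
    vit <- hmm_viterbi(model)
    post_az <- hmm_posterior(model)
    r <- rle(vit$path == 1L)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts_idx[k]; b <- ends_idx[k]
      n_snps <- b - a + 1L
      len_bp <- pos[b] - pos[a] + 1
      med <- stats::median(post_az[a:b])
      qual <- -10 * log10(max(1 - med, 1e-10))
      if (n_snps >= params$min_snp && qual > params$min_qual &&
          len_bp >= params$min_kb * 1000) {
        segs[[length(segs) + 1]] <- data.frame(
          sample = callset$sample_id, chrom = ch,
          start = pos[a], end = pos[b] + 1,
          n_snps = n_snps, length_bp = len_bp, source = "hmm",
          quality = qual, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      source = character(), quality = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
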