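#' Per-population ALT allele frequencies
#'
#' Frequency = ALT dosage sum / (2 x non-missing individuals), per site and
#' population; the observation count records how many individuals were
#' called.
#'
#' @param callsets named list of [new_callset()] objects sharing one site
#'   table.
#' @param groups named list mapping population name to sample ids.
#' @return List with `sites` and, per population, a data.frame column pair
#'   `freq` / `count` (as a list of two matrices `freq`, `count` with one
#'   column per population).
#' @export
group_freqs <- function(callsets, groups) {
  stopifnot(length(callsets) >= 1, length(groups) >= 1)
  if (any(lengths(groups) == 0)) stop("empty group")
  ids <- vapply(callsets, function(x) x$sample_id, "")
  names(callsets) <- ids
  for (cs in callsets) assert_same_sites(callsets[[1]], cs)
  n <- nrow(callsets[[1]]$sites)
  freq <- matrix(NA_real_, n, length(groups),
                 dimnames = list(NULL, names(groups)))
  count <- matrix(0L, n, length(groups),
                  dimnames = list(NULL, names(groups)))
  for (g in names(groups)) {
    miss <- setdiff(groups[[g]], ids)
    if (length(miss) > 0)
      stop("samples not found: ", paste(miss, collapse = ", "))
    d <- vapply(groups[[g]], function(s) callsets[[s]]$dosage, integer(n))
    d <- matrix(d, nrow = n)
    ac <- rowSums(d, na.rm = TRUE)
    nn <- rowSums(!is.na(d))
    count[, g] <- nn
    freq[, g] <- ifelse(nn > 0, ac / (2 * nn), NA_real_)
  }
  list(sites = callsets[[1]]$sites, freq = freq, count = count)
}

#' Outgroup f3 statistic with weighted block jackknife
#'
#' Estimates the shared drift of populations A and B relative to an outgroup
#' O as the mean over sites of `(o - a)(o - b)`, where o, a, b are ALT
#' allele frequencies. Sites missing in any of the three populations are
#' skipped. The standard error comes from a delete-one-block jackknife over
#' contiguous physical blocks of `block_size_bp`, weighted by block site
#' counts (the h_j = N/n_j convention), and z = f3/se. No finite-sample
#' bias correction is applied, the usual convention in outgroup mode.
#'
#' @param freqs result of [group_freqs()].
#' @param pop_o,pop_a,pop_b population names in `freqs`.
#' @param block_size_bp jackknife block size in bp (default 5 Mb).
#' @return List with `f3`, `se`, `z`, `n_sites`, `n_blocks`, and
#'   `loo` (data.frame of per-block delete-one estimates and site counts,
#'   useful for auditing the jackknife).
#' @export
outgroup_f3 <- function(freqs, pop_o, pop_a, pop_b, block_size_bp = 5e6) {
  for (p in c(pop_o, pop_a, pop_b))
    if (!p %in% colnames(freqs$freq)) stop("unknown population: ", p)
  o <- freqs$freq[, pop_o]; a <- freqs$freq[, pop_a]; b <- freqs$freq[, pop_b]
  use <- !is.na(o) & !is.na(a) & !is.na(b)
  if (!any(use)) stop("all sites skipped (missing in some population)")
  v <- (o[use] - a[use]) * (o[use] - b[use])
  sites <- freqs$sites[use, , drop = FALSE]
  block <- paste(sites$chrom, floor(sites$pos / block_size_bp))
  block <- factor(block, levels = unique(block))
  N <- length(v)
  f3 <- mean(v)
  nb <- nlevels(block)
  if (nb < 2) {
    return(list(f3 = f3, se = NA_real_, z = NA_real_, n_sites = N,
                n_blocks = nb, loo = NULL))
  }
  s_j <- tapply(v, block, sum)
  n_j <- tapply(rep(1, N), block, sum)
  theta_j <- (sum(v) - s_j) / (N - n_j)     # delete-one-block estimates
  h_j <- N / n_j
  theta_dot <- nb * f3 - sum((1 - n_j / N) * theta_j)
  tau_j <- h_j * f3 - (h_j - 1) * theta_j   # pseudovalues
  var_hat <- mean((tau_j - theta_dot)^2 / (h_j - 1))
  se <- sqrt(var_hat)
  list(f3 = f3, se = se, z = f3 / se, n_sites = N, n_blocks = nb,
       loo = data.frame(block = levels(block), n = as.integer(n_j),
                        theta = as.numeric(theta_j),
                        stringsAsFactors = FALSE))
}
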