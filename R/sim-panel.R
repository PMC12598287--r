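# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic haplotype panel
#'
#' The panel emulates a phased reference panel with linkage disequilibrium: a
#' small set of founder haplotypes is drawn site-by-site from Bernoulli(p)
#' with p ~ Beta(alpha, beta) (a U-shaped Beta gives the excess of rare
#' alleles typical of a site-frequency spectrum), and the remaining
#' haplotypes are recombinant mosaics of the founders, switching donor
#' between adjacent sites with probability `switch_rate_per_cM` times the
#' cM distance. Defaults are a desk-scale stand-in for a livestock panel:
#' two 50-Mb chromosomes at 1 cM/Mb with 50,000 sites each.
#'
#' @param n_founders number of founder haplotypes.
#' @param n_haplotypes total panel haplotypes (founders included).
#' @param n_sites sites per chromosome.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param founder_freq_alpha,founder_freq_beta Beta law for per-site founder
#'   allele frequency.
#' @param switch_rate_per_cM donor-switch probability per cM.
#' @param cm_per_mb linear recombination rate used to build the genetic map.
#' @param seed integer seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_founders = 20, n_haplotypes = 100,
                         n_sites = 50000,
                         chrom_lengths = c("1" = 5e7, "2" = 5e7),
                         founder_freq_alpha = 0.3, founder_freq_beta = 0.3,
                         switch_rate_per_cM = 0.05, cm_per_mb = 1,
                         seed = 1L) {
  stopifnot(n_founders >= 2, n_haplotypes >= n_founders, n_sites > 0,
            all(chrom_lengths > 0), founder_freq_alpha > 0,
            founder_freq_beta > 0, switch_rate_per_cM >= 0, cm_per_mb > 0)
  structure(list(n_founders = n_founders, n_haplotypes = n_haplotypes,
                 n_sites = n_sites, chrom_lengths = chrom_lengths,
                 founder_freq_alpha = founder_freq_alpha,
                 founder_freq_beta = founder_freq_beta,
                 switch_rate_per_cM = switch_rate_per_cM,
                 cm_per_mb = cm_per_mb, seed = as.integer(seed)),
            class = "panel_config")
}

# One mosaic haplotype copied from donor haplotypes along one chromosome.
# cm: cumulative cM per site; donors: matrix n_donors x n_sites.
mosaic_haplotype <- function(donors, cm, switch_rate) {
  n <- length(cm)
  p_switch <- pmin(1, switch_rate * c(0, diff(cm)))
  switched <- stats::runif(n) < p_switch
  switched[1] <- TRUE  # initial donor draw
  seg_id <- cumsum(switched)
  donor_of_seg <- sample.int(nrow(donors), max(seg_id), replace = TRUE)
  donors[cbind(donor_of_seg[seg_id], seq_len(n))]
}

#' Simulate a phased haplotype panel with LD
#'
#' @param config a [panel_config()].
#' @return List with `sites` (site table with extra columns `alt_freq` and
#'   `monomorphic`), `haplotypes` (0/1 matrix, haplotypes in rows, sites in
#'   columns, ordered like `sites`), `map` (genetic map), and the `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  if (sum(config$chrom_lengths) * config$cm_per_mb <= 0)
    stop("degenerate map: zero total cM")
  with_seed(config$seed, {
    chroms <- names(config$chrom_lengths)
    if (is.null(chroms)) chroms <- as.character(seq_along(config$chrom_lengths))
    site_list <- list(); hap_list <- list()
    for (ci in seq_along(config$chrom_lengths)) {
      len <- config$chrom_lengths[ci]
      pos <- sort(sample.int(len, config$n_sites)) - 1  # 0-based
      cm <- pos / 1e6 * config$cm_per_mb
      p <- stats::rbeta(config$n_sites, config$founder_freq_alpha,
                        config$founder_freq_beta)
      founders <- matrix(stats::rbinom(config$n_founders * config$n_sites,
                                       1, rep(p, each = config$n_founders)),
                         nrow = config$n_founders)
      H <- matrix(0L, nrow = config$n_haplotypes, ncol = config$n_sites)
      H[seq_len(config$n_founders), ] <- founders
      if (config$n_haplotypes > config$n_founders) {
        for (h in (config$n_founders + 1):config$n_haplotypes)
          H[h, ] <- mosaic_haplotype(founders, cm, config$switch_rate_per_cM)
      }
      ref <- sample(c("A", "C", "G", "T"), config$n_sites, replace = TRUE)
      alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
      site_list[[ci]] <- data.frame(chrom = chroms[ci], pos = pos, ref = ref,
                                    alt = alt, stringsAsFactors = FALSE)
      hap_list[[ci]] <- H
    }
    sd <- do.call(rbind, site_list)
    H <- do.call(cbind, hap_list)
    ord <- order(sd$chrom, sd$pos)  # align with new_sites() sort order
    sd <- sd[ord, , drop = FALSE]
    H <- H[, ord, drop = FALSE]
    alt_freq <- colMeans(H)
    sites <- new_sites(sd$chrom, sd$pos, sd$ref, sd$alt,
                       pmin(alt_freq, 1 - alt_freq))
    sites$alt_freq <- alt_freq
    sites$monomorphic <- sites$maf == 0
    map <- new_genetic_map(
      chrom = rep(chroms, each = 2),
      pos = as.numeric(rbind(0, config$chrom_lengths)),
      cm = as.numeric(rbind(0, config$chrom_lengths / 1e6 * config$cm_per_mb)))
    list(sites = sites, haplotypes = H, map = map, config = config)
  })
}
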