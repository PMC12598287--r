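#' Simulate truth diploids with planted ROH and IBD segments
#'
#' Each individual is built from two recombinant mosaic haplotypes copied
#' from the panel. Inside a planted ROH segment the second haplotype is
#' overwritten by the first, so the tract is exactly homozygous. Inside a
#' planted IBD segment both members of a pair carry one identical haplotype
#' copied from a common panel donor (on their first haplotype).
#'
#' @param panel result of [simulate_panel()].
#' @param n_individuals number of diploid individuals to create.
#' @param roh_plan optional data.frame with columns `sample` (1-based
#'   individual index), `chrom`, `start`, `end` (bp, 0-based half-open);
#'   per-sample segments must not overlap.
#' @param ibd_plan optional data.frame with columns `sample_a`, `sample_b`
#'   (1-based indices), `chrom`, `start`, `end`.
#' @param seed integer seed.
#' @return List with `callsets` (truth callsets, one per individual),
#'   `haplotypes` (per individual, a 2 x n_sites 0/1 matrix), and `manifest`
#'   (data.frame of planted segments: `kind`, `sample_a`, `sample_b`,
#'   `chrom`, `start`, `end`).
#' @export
simulate_truth <- function(panel, n_individuals, roh_plan = NULL,
                           ibd_plan = NULL, seed = 1L) {
  sites <- panel$sites
  lens <- panel$config$chrom_lengths
  chrom_names <- unique(sites$chrom)
  check_plan <- function(plan, cols) {
    if (is.null(plan)) return(invisible(NULL))
    stopifnot(all(cols %in% names(plan)))
    if (!all(plan$chrom %in% chrom_names))
      stop("plan references unknown chromosome")
    if (any(plan$start < 0) || any(plan$end <= plan$start))
      stop("plan segments must satisfy 0 <= start < end")
  }
  check_plan(roh_plan, c("sample", "chrom", "start", "end"))
  check_plan(ibd_plan, c("sample_a", "sample_b", "chrom", "start", "end"))
  if (!is.null(roh_plan)) {
    for (s in unique(roh_plan$sample)) {
      seg <- roh_plan[roh_plan$sample == s, ]
      for (ch in unique(seg$chrom)) {
        sc <- seg[seg$chrom == ch, ]
        sc <- sc[order(sc$start), ]
        if (nrow(sc) > 1 && any(sc$start[-1] < sc$end[-nrow(sc)]))
          stop("overlapping ROH plan segments for sample ", s)
      }
    }
  }
  cm <- unlist(lapply(chrom_names, function(ch)
    interpolate_cm(panel$map, ch, sites$pos[sites$chrom == ch])))
  site_chrom <- sites$chrom

  with_seed(seed, {
    haps <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      h <- matrix(0L, 2, nrow(sites))
      for (k in 1:2) for (ch in chrom_names) {
        idx <- which(site_chrom == ch)
        h[k, idx] <- mosaic_haplotype(panel$haplotypes[, idx, drop = FALSE],
                                      cm[idx],
                                      panel$config$switch_rate_per_cM)
      }
      haps[[i]] <- h
    }
    manifest <- data.frame(kind = character(), sample_a = character(),
                           sample_b = character(), chrom = character(),
                           start = numeric(), end = numeric(),
                           stringsAsFactors = FALSE)
    id_of <- function(i) sprintf("ind%02d", i)
    if (!is.null(ibd_plan)) for (r in seq_len(nrow(ibd_plan))) {
      sel <- site_chrom == ibd_plan$chrom[r] &
        sites$pos >= ibd_plan$start[r] & sites$pos < ibd_plan$end[r]
      donor <- panel$haplotypes[sample.int(nrow(panel$haplotypes), 1), sel]
      haps[[ibd_plan$sample_a[r]]][1, sel] <- donor
      haps[[ibd_plan$sample_b[r]]][1, sel] <- donor
      manifest <- rbind(manifest, data.frame(
        kind = "IBD", sample_a = id_of(ibd_plan$sample_a[r]),
        sample_b = id_of(ibd_plan$sample_b[r]), chrom = ibd_plan$chrom[r],
        start = ibd_plan$start[r], end = ibd_plan$end[r],
        stringsAsFactors = FALSE))
    }
    if (!is.null(roh_plan)) for (r in seq_len(nrow(roh_plan))) {
      sel <- site_chrom == roh_plan$chrom[r] &
        sites$pos >= roh_plan$start[r] & sites$pos < roh_plan$end[r]
      haps[[roh_plan$sample[r]]][2, sel] <- haps[[roh_plan$sample[r]]][1, sel]
      manifest <- rbind(manifest, data.frame(
        kind = "ROH", sample_a = id_of(roh_plan$sample[r]),
        sample_b = NA_character_, chrom = roh_plan$chrom[r],
        start = roh_plan$start[r], end = roh_plan$end[r],
        stringsAsFactors = FALSE))
    }
    callsets <- lapply(seq_len(n_individuals), function(i)
      new_callset(id_of(i), sites, haps[[i]][1, ] + haps[[i]][2, ]))
    names(callsets) <- vapply(callsets, function(x) x$sample_id, "")
    list(callsets = callsets, haplotypes = haps, manifest = manifest)
  })
}
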