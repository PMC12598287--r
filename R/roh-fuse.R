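#' Fuse HMM and window-scan ROH profiles
#'
#' The two callers have opposing biases: the window scan is conservative on
#' long runs at low SNP density while the HMM recovers long runs well but
#' over-calls short stretches. The fusion rule keeps only HMM segments
#' strictly longer than `long_threshold_bp` (default 4 Mb) and merges them
#' into the full window-scan profile, combining overlapping or touching
#' intervals. Each fused segment records how many input segments it
#' collapses and their lengths (the mergeBed `-o count, collapse`
#' accounting).
#'
#' @param windowscan_segs,hmm_segs segment data.frames for one sample from
#'   [windowscan_roh()] and [hmm_roh()].
#' @param long_threshold_bp minimum (exclusive) HMM segment length.
#' @return Segment data.frame with `source = "merged"`, `n_sources` and
#'   `collapsed_lengths` (comma-separated bp) columns; `n_snps` is summed
#'   over contributing segments.
#' @export
fuse_roh <- function(windowscan_segs, hmm_segs, long_threshold_bp = 4e6) {
  long_hmm <- hmm_segs[hmm_segs$length_bp > long_threshold_bp, , drop = FALSE]
  cols <- c("sample", "chrom", "start", "end", "n_snps", "length_bp")
  pool <- rbind(windowscan_segs[, cols, drop = FALSE],
                long_hmm[, cols, drop = FALSE])
  if (nrow(pool) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_snps = integer(),
                      length_bp = numeric(), source = character(),
                      n_sources = integer(), collapsed_lengths = character(),
                      stringsAsFactors = FALSE))
  if (length(unique(pool$sample)) > 1)
    stop("fuse_roh expects segments of a single sample")
  pool <- pool[order(pool$chrom, pool$start, pool$end), , drop = FALSE]
  out <- list()
  cur <- pool[1, ]
  members <- list(pool[1, ])
  flush <- function(cur, members) {
    m <- do.call(rbind, members)
    data.frame(sample = cur$sample, chrom = cur$chrom, start = cur$start,
               end = cur$end, n_snps = sum(m$n_snps),
               length_bp = cur$end - cur$start, source = "merged",
               n_sources = nrow(m),
               collapsed_lengths = paste(format(m$length_bp,
                                                scientific = FALSE,
                                                trim = TRUE),
                                         collapse = ","),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pool))[-1]) {
    if (pool$chrom[i] == cur$chrom && pool$start[i] <= cur$end) {
      cur$end <- max(cur$end, pool$end[i])
      members[[length(members) + 1]] <- pool[i, ]
    } else {
      out[[length(out) + 1]] <- flush(cur, members)
      cur <- pool[i, ]
      members <- list(pool[i, ])
    }
  }
  out[[length(out) + 1]] <- flush(cur, members)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative ROH per length bin
#'
#' Sums segment lengths (in Mb) within length bins — the standard ROH-profile
#' summary whose short bins reflect background relatedness and whose long
#' bins reflect recent inbreeding.
#'
#' @param segments a segment data.frame (any caller).
#' @param bins increasing bin edges in bp; default 0.5, 1, 2, 4, 8 Mb and
#'   infinity. Segments shorter than the first edge are tallied in an
#'   `"<first"` under-bin.
#' @return data.frame with one row per bin (`bin`, `mb`) plus attribute
#'   `total_mb`.
#' @export
roh_summary <- function(segments,
                        bins = c(0.5e6, 1e6, 2e6, 4e6, 8e6, Inf)) {
  stopifnot(!is.unsorted(bins, strictly = TRUE))
  edges <- c(0, bins)
  labs <- c(paste0("<", bins[1] / 1e6),
            paste0("(", edges[2:(length(edges) - 1)] / 1e6, ",",
                   edges[3:length(edges)] / 1e6, "]"))
  bin_of <- cut(segments$length_bp, breaks = edges, labels = labs,
                right = TRUE, include.lowest = TRUE)
  mb <- tapply(segments$length_bp / 1e6, bin_of, sum)
  mb[is.na(mb)] <- 0
  out <- data.frame(bin = labs, mb = as.numeric(mb[labs]),
                    stringsAsFactors = FALSE)
  out$mb[is.na(out$mb)] <- 0
  attr(out, "total_mb") <- sum(out$mb)
  if (out$mb[1] > 0)
    attr(out, "under_bin_flag") <- TRUE
  out
}

#' Downsample a callset to a fixed number of called sites
#'
#' Uniform random subset of the non-missing sites, order preserved — the
#' device used to match SNP density across samples before ROH calling and to
#' study density-driven ROH fragmentation.
#'
#' @param callset a [new_callset()].
#' @param n target number of sites (at most the number of non-missing calls).
#' @param seed integer seed.
#' @return A callset restricted to the sampled sites.
#' @export
downsample_sites <- function(callset, n, seed = 1L) {
  nonmiss <- which(!is.na(callset$dosage))
  if (n > length(nonmiss))
    stop("n exceeds the number of non-missing sites (", length(nonmiss), ")")
  with_seed(seed, {
    keep <- sort(sample(nonmiss, n))
    subset_callset(callset, keep)
  })
}
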