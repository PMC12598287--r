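#' Sliding windows over chromosomes
#'
#' Generates windows in the bedtools-makewindows dialect: per chromosome,
#' starts at 0, step, 2*step, ... while start < length, with the final
#' windows truncated at the chromosome end. The genome scans use 500 kb
#' windows with a 100 kb step.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step between window starts in bp.
#' @return data.frame of intervals `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
make_windows <- function(chrom_lengths, size = 5e5, step = 1e5) {
  stopifnot(size > 0, step > 0)
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) chroms <- as.character(seq_along(chrom_lengths))
  out <- lapply(seq_along(chrom_lengths), function(i) {
    len <- chrom_lengths[i]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = chroms[i], start = starts,
               end = pmin(starts + size, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-window event rates
#'
#' Aggregates per-site event flags into rates per (possibly overlapping)
#' window: a site contributes to every window containing its position.
#' `in_denom`/`in_num` follow the bedtools-map accounting of "correct and
#' total genotypes per window".
#'
#' @param sites site table (sorted).
#' @param in_denom,in_num logical vectors aligned to `sites`: membership in
#'   the rate's denominator and numerator (`in_num` implies `in_denom`).
#' @param windows interval data.frame from [make_windows()].
#' @return `windows` with added columns `n_total`, `n_event` and `rate`
#'   (`NA` where `n_total` is 0).
#' @export
window_rates <- function(sites, in_denom, in_num, windows) {
  stopifnot(length(in_denom) == nrow(sites), length(in_num) == nrow(sites))
  if (any(in_num & !in_denom)) stop("in_num must imply in_denom")
  windows$n_total <- 0L
  windows$n_event <- 0L
  for (ch in unique(windows$chrom)) {
    sel <- sites$chrom == ch
    pos <- sites$pos[sel]
    wd <- which(windows$chrom == ch)
    # prefix counts over sorted positions
    cum_d <- cumsum(in_denom[sel])
    cum_n <- cumsum(in_num[sel])
    at <- function(cum, x) ifelse(x > 0, cum[pmax(x, 1)], 0)
    lo <- findInterval(windows$start[wd] - 0.5, pos)   # sites with pos < start
    hi <- findInterval(windows$end[wd] - 0.5, pos)     # sites with pos < end
    windows$n_total[wd] <- at(cum_d, hi) - at(cum_d, lo)
    windows$n_event[wd] <- at(cum_n, hi) - at(cum_n, lo)
  }
  windows$rate <- ifelse(windows$n_total > 0,
                         windows$n_event / windows$n_total, NA_real_)
  windows
}

# merge overlapping or touching intervals (bedtools-merge dialect);
# returns merged intervals, optionally with an aggregation over payloads
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[, c("chrom", "start", "end")])
  iv <- intervals[order(intervals$chrom, intervals$start, intervals$end), ]
  out <- list()
  cur <- iv[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$chrom[i] == cur$chrom && iv$start[i] <= cur$end) {
      cur$end <- max(cur$end, iv$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- iv[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentile outlier regions of a window scan
#'
#' Ranks windows with a defined rate and selects the extreme tail by the
#' nearest-rank (ceiling) percentile: the bottom tail for concordance-style
#' metrics, the top tail for FPR-style metrics. All windows tied at the
#' threshold rank are selected (and flagged via the `tied` attribute).
#' Selected windows that overlap or touch are merged into regions.
#'
#' @param stats a [window_rates()] result.
#' @param tail `"bottom"` or `"top"`.
#' @param pct tail size in percent (default 1).
#' @return Merged interval data.frame; attribute `threshold` carries the
#'   rate cutoff, attribute `tied` whether ties widened the selection.
#' @export
percentile_outliers <- function(stats, tail = c("bottom", "top"), pct = 1) {
  tail <- match.arg(tail)
  def <- stats[!is.na(stats$rate), , drop = FALSE]
  n <- nrow(def)
  if (n < 100 / pct)
    warning("fewer than ", ceiling(100 / pct),
            " defined windows; percentile is coarse")
  if (n == 0) return(def[, c("chrom", "start", "end")])
  k <- max(1L, ceiling(pct / 100 * n))
  sorted <- sort(def$rate, decreasing = (tail == "top"))
  thr <- sorted[k]
  sel <- if (tail == "bottom") def$rate <= thr else def$rate >= thr
  tied <- sum(sel) > k
  out <- merge_intervals(def[sel, , drop = FALSE])
  attr(out, "threshold") <- thr
  attr(out, "tied") <- tied
  out
}

#' Regions recurrently outlying across samples
#'
#' Merges all samples' outlier intervals into regions and keeps those to
#' which at least `min_samples` samples contribute (a sample contributes if
#' any of its intervals overlaps the region).
#'
#' @param per_sample_outliers named list of interval data.frames.
#' @param min_samples minimum contributing samples (default 3, "a majority").
#' @return Interval data.frame with a `n_samples` column.
#' @export
recurrent_regions <- function(per_sample_outliers, min_samples = 3) {
  if (length(per_sample_outliers) < min_samples)
    stop("need at least ", min_samples, " outlier sets")
  all_iv <- do.call(rbind, lapply(per_sample_outliers, function(x)
    x[, c("chrom", "start", "end")]))
  if (nrow(all_iv) == 0)
    return(cbind(all_iv, n_samples = integer(0)))
  merged <- merge_intervals(all_iv)
  merged$n_samples <- vapply(seq_len(nrow(merged)), function(i) {
    sum(vapply(per_sample_outliers, function(iv) {
      any(iv$chrom == merged$chrom[i] & iv$start < merged$end[i] &
            iv$end > merged$start[i])
    }, logical(1)))
  }, integer(1))
  out <- merged[merged$n_samples >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heterozygosity in consecutive 50-SNP windows
#'
#' Segments a callset's non-missing calls into consecutive, non-overlapping
#' blocks of exactly `window_snps` calls per chromosome (the trailing partial
#' block is dropped) and counts heterozygous calls per block.
#'
#' @param callset a [new_callset()] object.
#' @param window_snps block size in SNPs (default 50).
#' @return data.frame `chrom`, `start`, `end` (bp span of the block),
#'   `n_het`.
#' @export
het_windows <- function(callset, window_snps = 50) {
  out <- list()
  for (ch in unique(callset$sites$chrom)) {
    sel <- which(callset$sites$chrom == ch & !is.na(callset$dosage))
    n_blocks <- length(sel) %/% window_snps
    if (n_blocks == 0) next
    idx <- sel[seq_len(n_blocks * window_snps)]
    blk <- rep(seq_len(n_blocks), each = window_snps)
    het <- callset$dosage[idx] == 1L
    out[[length(out) + 1]] <- data.frame(
      chrom = ch,
      start = tapply(callset$sites$pos[idx], blk, min),
      end = tapply(callset$sites$pos[idx], blk, max) + 1,
      n_het = as.integer(tapply(het, blk, sum)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_het = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove sites falling in excluded regions
#'
#' Drops, from one or more callsets consistently, every site whose position
#' lies inside any of the given intervals (used to excise recurrent
#' low-quality regions before downstream analyses).
#'
#' @param callsets a callset or list of callsets sharing one site table.
#' @param regions interval data.frame (`chrom`, `start`, `end`).
#' @return The filtered callset(s), same shape as the input.
#' @export
exclude_regions <- function(callsets, regions) {
  single <- inherits(callsets, "callset")
  if (single) callsets <- list(callsets)
  sites <- callsets[[1]]$sites
  drop <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(regions))) {
    drop <- drop | (sites$chrom == regions$chrom[i] &
                      sites$pos >= regions$start[i] &
                      sites$pos < regions$end[i])
  }
  out <- lapply(callsets, subset_callset, idx = which(!drop))
  if (single) out[[1]] else out
}
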