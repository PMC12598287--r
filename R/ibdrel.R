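#' Relatedness criteria for pairwise IBD sharing
#'
#' A pair is called related (up to roughly the 8th degree) when it shares at
#' least `min_segments` IBD segments each strictly longer than
#' `min_segment_cM`, with a cumulative length over those qualifying segments
#' of at least `min_total_cM`.
#'
#' @param min_segments minimum qualifying segment count (default 3).
#' @param min_segment_cM strict per-segment length threshold (default 3).
#' @param min_total_cM inclusive cumulative threshold (default 21).
#' @return A `relatedness_criteria` list.
#' @export
relatedness_criteria <- function(min_segments = 3, min_segment_cM = 3,
                                 min_total_cM = 21) {
  stopifnot(min_segments > 0, min_segment_cM > 0, min_total_cM > 0)
  structure(list(min_segments = min_segments,
                 min_segment_cM = min_segment_cM,
                 min_total_cM = min_total_cM),
            class = "relatedness_criteria")
}

# canonical pair key: alphabetical order
canonical_pairs <- function(seg) {
  a <- pmin(seg$sample_a, seg$sample_b)
  b <- pmax(seg$sample_a, seg$sample_b)
  seg$sample_a <- a
  seg$sample_b <- b
  seg
}

# remove the portions of segments that fall inside excluded regions,
# splitting a segment when a region sits strictly inside it
subtract_regions <- function(seg, regions) {
  if (is.null(regions) || nrow(regions) == 0 || nrow(seg) == 0) return(seg)
  pieces <- list(seg)
  for (r in seq_len(nrow(regions))) {
    nxt <- list()
    for (df in pieces) {
      hit <- df$chrom == regions$chrom[r] & df$start < regions$end[r] &
        df$end > regions$start[r]
      keep <- df[!hit, , drop = FALSE]
      ov <- df[hit, , drop = FALSE]
      left <- ov[ov$start < regions$start[r], , drop = FALSE]
      left$end <- rep(regions$start[r], nrow(left))
      right <- ov[ov$end > regions$end[r], , drop = FALSE]
      right$start <- rep(regions$end[r], nrow(right))
      nxt[[length(nxt) + 1]] <- rbind(keep, left, right)
    }
    pieces <- nxt
  }
  out <- do.call(rbind, pieces)
  out[out$end > out$start, , drop = FALSE]
}

# attach cM coordinates via the genetic map
ibd_add_cm <- function(seg, map) {
  if (nrow(seg) == 0) {
    seg$start_cm <- numeric(0); seg$end_cm <- numeric(0)
    seg$length_cm <- numeric(0)
    return(seg)
  }
  seg$start_cm <- NA_real_
  seg$end_cm <- NA_real_
  for (ch in unique(seg$chrom)) {
    i <- seg$chrom == ch
    seg$start_cm[i] <- interpolate_cm(map, ch, seg$start[i])
    seg$end_cm[i] <- interpolate_cm(map, ch, seg$end[i])
  }
  seg$length_cm <- seg$end_cm - seg$start_cm
  seg
}

#' Combine repeated IBD detection runs
#'
#' Pools the segment tables of repeated detection runs for each sample pair:
#' records with LOD below `lod_min` are dropped first, excluded regions (by
#' default the first 2 Mb of chromosome 18, a suspected assembly artifact
#' with an extreme apparent recombination rate) are excised, then per pair
#' and chromosome the surviving segments are unioned (overlapping or
#' touching intervals merge), and merged segments shorter than `len_min_cM`
#' are removed.
#'
#' @param run_tables list of data.frames in [read_ibd_table()] layout.
#' @param map genetic map for cM lengths.
#' @param lod_min minimum LOD (inclusive) applied before the union.
#' @param len_min_cM minimum merged-segment length in cM (inclusive).
#' @param exclude interval data.frame of regions to excise; `NULL` for none.
#' @return data.frame of per-pair segments: `sample_a`, `sample_b`, `chrom`,
#'   `start`, `end`, `start_cm`, `end_cm`, `length_cm`.
#' @export
combine_runs <- function(run_tables, map, lod_min = 3, len_min_cM = 3,
                         exclude = data.frame(chrom = "18", start = 0,
                                              end = 2e6)) {
  stopifnot(length(run_tables) >= 1)
  all_seg <- do.call(rbind, run_tables)
  all_seg <- all_seg[all_seg$lod >= lod_min, , drop = FALSE]
  all_seg <- canonical_pairs(all_seg)
  all_seg <- subtract_regions(all_seg, exclude)
  out <- list()
  if (nrow(all_seg) > 0) {
    key <- paste(all_seg$sample_a, all_seg$sample_b, sep = "\r")
    for (k in unique(key)) {
      sub <- all_seg[key == k, , drop = FALSE]
      merged <- merge_intervals(sub[, c("chrom", "start", "end")])
      merged$sample_a <- sub$sample_a[1]
      merged$sample_b <- sub$sample_b[1]
      out[[length(out) + 1]] <- merged
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               sample_a = character(), sample_b = character(),
               stringsAsFactors = FALSE)
  res <- res[, c("sample_a", "sample_b", "chrom", "start", "end")]
  res <- ibd_add_cm(res, map)
  res <- res[res$length_cm >= len_min_cM, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge gapped segments of one pair in cM space
#'
#' Consecutive segments of the same pair and chromosome separated by a gap
#' strictly shorter than `max_gap_cM` are merged into one spanning segment
#' (transitively). The default 0.6 cM closes the short phasing breaks that
#' split true IBD tracts; a validation mode against duplicate genotypes
#' would use a wider gap (e.g. 4 cM).
#'
#' @param segments per-pair segment data.frame from [combine_runs()].
#' @param max_gap_cM strict gap threshold in cM.
#' @param map genetic map (to refresh cM columns after merging).
#' @return Merged segment data.frame, same layout.
#' @export
merge_pair_segments <- function(segments, max_gap_cM = 0.6, map = NULL) {
  if (nrow(segments) == 0) return(segments)
  key <- paste(segments$sample_a, segments$sample_b, segments$chrom,
               sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- segments[key == k, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur <- sub[1, ]
    for (i in seq_len(nrow(sub))[-1]) {
      gap <- sub$start_cm[i] - cur$end_cm
      # strict threshold, guarded against interpolation round-off
      if (gap < max_gap_cM - 1e-9) {
        cur$end <- max(cur$end, sub$end[i])
        cur$end_cm <- max(cur$end_cm, sub$end_cm[i])
      } else {
        out[[length(out) + 1]] <- cur
        cur <- sub[i, ]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  res <- do.call(rbind, out)
  res$length_cm <- res$end_cm - res$start_cm
  if (!is.null(map)) res <- ibd_add_cm(res[, setdiff(names(res),
    c("start_cm", "end_cm", "length_cm"))], map)
  res <- res[order(res$sample_a, res$sample_b, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Classify a pair as related from its merged IBD segments
#'
#' @param pair_segments merged segments of one sample pair.
#' @param criteria a [relatedness_criteria()].
#' @return `TRUE` iff the pair meets the criteria.
#' @export
classify_related <- function(pair_segments,
                             criteria = relatedness_criteria()) {
  stopifnot(inherits(criteria, "relatedness_criteria"))
  qual <- pair_segments$length_cm > criteria$min_segment_cM
  sum(qual) >= criteria$min_segments &&
    sum(pair_segments$length_cm[qual]) >= criteria$min_total_cM
}

#' Classify every pair in a segment table
#'
#' @param segments merged per-pair segments (all pairs together).
#' @param criteria a [relatedness_criteria()].
#' @return data.frame `sample_a`, `sample_b`, `n_segments`, `total_cm`,
#'   `related`.
#' @export
classify_all_pairs <- function(segments,
                               criteria = relatedness_criteria()) {
  if (nrow(segments) == 0)
    return(data.frame(sample_a = character(), sample_b = character(),
                      n_segments = integer(), total_cm = numeric(),
                      related = logical(), stringsAsFactors = FALSE))
  key <- paste(segments$sample_a, segments$sample_b, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sub <- segments[key == k, , drop = FALSE]
    qual <- sub$length_cm > criteria$min_segment_cM
    data.frame(sample_a = sub$sample_a[1], sample_b = sub$sample_b[1],
               n_segments = sum(qual), total_cm = sum(sub$length_cm[qual]),
               related = classify_related(sub, criteria),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalized within-group relatedness
#'
#' Fraction of a group's individuals that have at least one related partner
#' inside the group — 1 when every individual is related to someone, 0 when
#' none is. Defined for groups of at least three samples. The alternative
#' pair-level definition (fraction of related pairs) is available via
#' `level = "pair"`.
#'
#' @param group_samples character vector of sample ids (>= 3).
#' @param pair_classifications data.frame from [classify_all_pairs()];
#'   pairs absent from the table count as unrelated.
#' @param level `"individual"` (default) or `"pair"`.
#' @return Fraction in `[0, 1]`.
#' @export
normalized_relatedness <- function(group_samples, pair_classifications,
                                   level = c("individual", "pair")) {
  level <- match.arg(level)
  if (length(group_samples) < 3)
    stop("normalized relatedness requires a group of at least 3 samples")
  pc <- pair_classifications
  inside <- pc$sample_a %in% group_samples & pc$sample_b %in% group_samples &
    pc$related
  if (level == "pair") {
    n_pairs <- choose(length(group_samples), 2)
    return(sum(inside) / n_pairs)
  }
  with_rel <- unique(c(pc$sample_a[inside], pc$sample_b[inside]))
  length(intersect(with_rel, group_samples)) / length(group_samples)
}

#' Between-group cumulative IBD matrix
#'
#' Entry (g, h) is the total merged IBD length in cM summed over all pairs
#' with one member in g and one in h; the diagonal holds the within-group
#' total. Symmetric by construction.
#'
#' @param groups named list of character vectors of sample ids (disjoint).
#' @param segments merged per-pair segments (all pairs).
#' @return Numeric matrix with group names on both dimensions.
#' @export
between_group_ibd <- function(groups, segments) {
  ids <- unlist(groups)
  if (anyDuplicated(ids)) stop("groups must be disjoint")
  g_of <- rep(names(groups), lengths(groups))
  names(g_of) <- ids
  k <- length(groups)
  m <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  if (nrow(segments) == 0) return(m)
  ga <- g_of[segments$sample_a]
  gb <- g_of[segments$sample_b]
  ok <- !is.na(ga) & !is.na(gb)
  for (i in which(ok)) {
    m[ga[i], gb[i]] <- m[ga[i], gb[i]] + segments$length_cm[i]
    if (ga[i] != gb[i])
      m[gb[i], ga[i]] <- m[gb[i], ga[i]] + segments$length_cm[i]
  }
  m
}
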