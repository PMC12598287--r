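#' Emit noisy IBD segment tables from a planted-segment manifest
#'
#' Emulates the output of repeated haplotype-based IBD detection runs over
#' the same samples: every planted IBD tract appears in every run with its
#' boundaries jittered in cM space, optionally split into two pieces
#' separated by a gap shorter than the downstream merge threshold. Decoy
#' negatives are added per run: short segments (< 3 cM, passing LOD) and
#' low-LOD segments (LOD < 3, passing length) between pairs that share no
#' planted tract, so that none of them survives the standard combine/filter
#' stage.
#'
#' @param manifest data.frame of planted segments as produced by
#'   [simulate_truth()]; rows with `kind == "IBD"` are used.
#' @param map genetic map covering the manifest chromosomes.
#' @param samples character vector of all sample ids (decoy pairs are drawn
#'   from these); defaults to the samples in the manifest.
#' @param n_runs number of detection runs to emulate.
#' @param split_prob probability a tract is emitted as two pieces separated
#'   by a gap < 0.6 cM.
#' @param jitter_cm boundary jitter, uniform in `[-jitter_cm, jitter_cm]`.
#' @param lod_law function(n) drawing n LOD scores for true segments.
#' @param decoys_per_run number of decoy segments of each flavour per run.
#' @param seed integer seed.
#' @return List of `n_runs` data.frames in [read_ibd_table()] layout.
#' @export
emit_ibd_tables <- function(manifest, map, samples = NULL, n_runs = 3,
                            split_prob = 0.3, jitter_cm = 0.2,
                            lod_law = function(n) 3 + stats::rexp(n, 1 / 5),
                            decoys_per_run = 5, seed = 1L) {
  stopifnot(n_runs >= 1, split_prob >= 0, split_prob <= 1, jitter_cm >= 0)
  ibd <- manifest[manifest$kind == "IBD", , drop = FALSE]
  if (is.null(samples))
    samples <- sort(unique(c(ibd$sample_a, ibd$sample_b)))
  chroms <- unique(map$chrom)
  chrom_span <- lapply(chroms, function(ch) {
    sub <- map[map$chrom == ch, ]
    c(cm_min = min(sub$cm), cm_max = max(sub$cm))
  })
  names(chrom_span) <- chroms

  planted_key <- paste(pmin(ibd$sample_a, ibd$sample_b),
                       pmax(ibd$sample_a, ibd$sample_b))
  seg_row <- function(a, b, ch, s_cm, e_cm, lod) {
    data.frame(sample_a = a, hap_a = sample(1:2, 1), sample_b = b,
               hap_b = sample(1:2, 1), chrom = ch,
               start = round(interpolate_bp(map, ch, s_cm)),
               end = round(interpolate_bp(map, ch, e_cm)),
               lod = lod, stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      rows <- list()
      for (i in seq_len(nrow(ibd))) {
        ch <- ibd$chrom[i]
        span <- chrom_span[[ch]]
        s_cm <- interpolate_cm(map, ch, ibd$start[i]) +
          stats::runif(1, -jitter_cm, jitter_cm)
        e_cm <- interpolate_cm(map, ch, ibd$end[i]) +
          stats::runif(1, -jitter_cm, jitter_cm)
        s_cm <- max(span["cm_min"], s_cm)
        e_cm <- min(span["cm_max"], e_cm)
        if (e_cm - s_cm < 0.1) next
        if (stats::runif(1) < split_prob && e_cm - s_cm > 2) {
          mid <- stats::runif(1, s_cm + 0.2 * (e_cm - s_cm),
                              e_cm - 0.2 * (e_cm - s_cm))
          gap <- stats::runif(1, 0.05, 0.55)  # strictly < 0.6 cM
          rows[[length(rows) + 1]] <- seg_row(
            ibd$sample_a[i], ibd$sample_b[i], ch, s_cm,
            max(s_cm + 0.05, mid - gap / 2), lod_law(1))
          rows[[length(rows) + 1]] <- seg_row(
            ibd$sample_a[i], ibd$sample_b[i], ch,
            min(e_cm - 0.05, mid + gap / 2), e_cm, lod_law(1))
        } else {
          rows[[length(rows) + 1]] <- seg_row(
            ibd$sample_a[i], ibd$sample_b[i], ch, s_cm, e_cm, lod_law(1))
        }
      }
      # decoys between pairs with no planted tract
      decoy_pair <- function() {
        for (tries in 1:50) {
          p <- sample(samples, 2)
          if (!(paste(min(p), max(p)) %in% planted_key)) return(p)
        }
        NULL
      }
      for (k in seq_len(decoys_per_run)) {
        p <- decoy_pair()
        if (is.null(p)) break
        ch <- sample(chroms, 1)
        span <- chrom_span[[ch]]
        # short decoy: < 3 cM, credible LOD
        len <- stats::runif(1, 0.5, 2.9)
        s <- stats::runif(1, span["cm_min"], span["cm_max"] - len)
        rows[[length(rows) + 1]] <- seg_row(p[1], p[2], ch, s, s + len,
                                            lod_law(1))
        # low-LOD decoy: long enough, LOD < 3
        len <- stats::runif(1, 3.5, 8)
        s <- stats::runif(1, span["cm_min"],
                          max(span["cm_min"] + 0.1, span["cm_max"] - len))
        rows[[length(rows) + 1]] <- seg_row(p[1], p[2], ch, s,
                                            min(s + len, span["cm_max"]),
                                            stats::runif(1, 0.5, 2.9))
      }
      runs[[r]] <- if (length(rows) > 0) do.call(rbind, rows) else
        data.frame(sample_a = character(), hap_a = integer(),
                   sample_b = character(), hap_b = integer(),
                   chrom = character(), start = numeric(), end = numeric(),
                   lod = numeric(), stringsAsFactors = FALSE)
      rownames(runs[[r]]) <- NULL
    }
    runs
  })
}
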