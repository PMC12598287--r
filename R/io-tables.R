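#' Read a BED file of intervals
#'
#' BED3/BED6, 0-based half-open, passed through unchanged (matching the
#' package's internal convention). Columns beyond the third are kept as a
#' `payload` (column 4, the BED name/score slot) when present.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end` and optionally
#'   `payload`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed BED line(s): ", paste(which(nf < 3), collapse = ", "))
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stop("non-numeric BED coordinates at line(s): ",
         paste(which(is.na(out$start) | is.na(out$end)), collapse = ", "))
  if (any(out$start < 0 | out$start >= out$end))
    stop("BED intervals must satisfy 0 <= start < end")
  if (any(nf >= 4)) out$payload <- vapply(parts, function(p)
    if (length(p) >= 4) p[4] else NA_character_, "")
  out
}

#' Write intervals to a BED file
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   further columns (written as BED columns 4+).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  df <- intervals[, c("chrom", "start", "end",
                      setdiff(names(intervals), c("chrom", "start", "end"))),
                  drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an IBD segment table
#'
#' Eight tab-separated columns in the RefinedIBD output dialect:
#' sample1, haplotype1, sample2, haplotype2, chromosome, start (bp),
#' end (bp), LOD score.
#'
#' @param path file path.
#' @return data.frame with columns `sample_a`, `hap_a`, `sample_b`, `hap_b`,
#'   `chrom`, `start`, `end`, `lod`.
#' @export
read_ibd_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0)
    return(data.frame(sample_a = character(), hap_a = integer(),
                      sample_b = character(), hap_b = integer(),
                      chrom = character(), start = numeric(), end = numeric(),
                      lod = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) != 8)
  if (length(bad) > 0)
    stop("malformed IBD line(s) (expect 8 tab-separated columns): ",
         paste(bad, collapse = ", "))
  m <- do.call(rbind, parts)
  out <- data.frame(
    sample_a = m[, 1], hap_a = as.integer(m[, 2]),
    sample_b = m[, 3], hap_b = as.integer(m[, 4]),
    chrom = m[, 5], start = as.numeric(m[, 6]), end = as.numeric(m[, 7]),
    lod = as.numeric(m[, 8]), stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end) || anyNA(out$lod))
    stop("non-numeric coordinates or LOD in IBD table ", path)
  if (any(out$start >= out$end))
    stop("IBD segments must satisfy start < end")
  out
}

#' Write an IBD segment table
#' @param segments data.frame as returned by [read_ibd_table()].
#' @param path output path.
#' @export
write_ibd_table <- function(segments, path) {
  df <- segments[, c("sample_a", "hap_a", "sample_b", "hap_b", "chrom",
                     "start", "end", "lod")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
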