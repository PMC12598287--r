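#' Genetic maps: bp to centimorgan conversion
#'
#' A genetic map is stored as a data.frame of anchors with columns `chrom`,
#' `pos` (bp) and `cm` (cumulative centimorgans), strictly increasing in `pos`
#' and non-decreasing in `cm` within each chromosome. Physical coordinates are
#' converted to recombination distance by piecewise-linear interpolation, the
#' convention shared by IBD segment lengths and HMM transition scaling.
#'
#' @param chrom,pos,cm anchor columns.
#' @return A `genetic_map` data.frame.
#' @export
new_genetic_map <- function(chrom, pos, cm) {
  m <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  cm = as.numeric(cm), stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (any(diff(sub$pos) <= 0))
      stop("map positions must be strictly increasing on chromosome ", ch)
    if (any(diff(sub$cm) < 0))
      stop("map cM must be non-decreasing on chromosome ", ch)
  }
  rownames(m) <- NULL
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Interpolate cumulative cM at physical positions
#'
#' Piecewise-linear interpolation between flanking anchors; positions beyond
#' the terminal anchors take the terminal anchor's cM (constant
#' extrapolation), so output is monotone non-decreasing in position.
#'
#' @param map a [new_genetic_map()] object.
#' @param chrom chromosome label (scalar).
#' @param pos numeric vector of bp positions.
#' @return Numeric vector of cumulative cM.
#' @export
interpolate_cm <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("chromosome ", chrom, " absent from map (or has < 2 anchors)")
  stats::approx(sub$pos, sub$cm, xout = pos, rule = 2, ties = "ordered")$y
}

#' Invert a genetic map: bp position at a cumulative cM
#'
#' Inverse of [interpolate_cm()] (requires strictly increasing cM on the
#' chromosome); used when segment boundaries are manipulated in cM space.
#'
#' @inheritParams interpolate_cm
#' @param cm numeric vector of cumulative cM values.
#' @return Numeric vector of bp positions.
#' @export
interpolate_bp <- function(map, chrom, cm) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("chromosome ", chrom, " absent from map (or has < 2 anchors)")
  if (any(diff(sub$cm) <= 0))
    stop("map not invertible on chromosome ", chrom, " (flat cM)")
  stats::approx(sub$cm, sub$pos, xout = cm, rule = 2, ties = "ordered")$y
}

#' Read a genetic map file
#'
#' Three whitespace-separated columns: chromosome, position (bp), cumulative
#' cM. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A `genetic_map` object.
#' @export
read_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("chrom", "pos", "cm"),
                           colClasses = c("character", "numeric", "numeric"))
  new_genetic_map(tab$chrom, tab$pos, tab$cm)
}

#' Write a genetic map file
#' @param map a `genetic_map` object.
#' @param path file path.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("chrom", "pos", "cm")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
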