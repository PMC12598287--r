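#' Construct a site table
#'
#' A site table is the unit of all stratification in the package: one row per
#' biallelic autosomal SNP, carrying the panel minor-allele frequency and the
#' substitution class. Positions are stored 0-based internally (half-open
#' interval convention); VCF coordinates are converted at the boundary.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos numeric vector of 0-based positions.
#' @param ref,alt single-character alleles (A/C/G/T), `ref != alt` per site.
#' @param maf panel minor-allele frequency in `[0, 0.5]`.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `maf`,
#'   `subst_class`, sorted by chromosome then position.
#' @export
new_sites <- function(chrom, pos, ref, alt, maf) {
  n <- length(pos)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(ref) == 1) ref <- rep(ref, n)
  if (length(alt) == 1) alt <- rep(alt, n)
  if (length(maf) == 1) maf <- rep(maf, n)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            length(maf) == n)
  if (any(pos < 0)) stop("site positions must be >= 0 (0-based)")
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  sites <- data.frame(
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = as.character(ref), alt = as.character(alt),
    maf = as.numeric(maf),
    subst_class = classify_substitution(ref, alt),
    stringsAsFactors = FALSE
  )
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate site positions within a chromosome")
  rownames(sites) <- NULL
  sites
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-purine (A<->G) and pyrimidine-pyrimidine
#' (C<->T) exchanges; all other pairs are transversions. Transitions are the
#' class confounded by postmortem cytosine deamination in ancient DNA, hence
#' accuracy is stratified on this label throughout.
#'
#' @param ref,alt character vectors of single alleles in A/C/G/T.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G")  # transition
#' classify_substitution("A", "C")  # transversion
#' @export
classify_substitution <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("alleles must be A, C, G or T")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  purine <- function(x) x %in% c("A", "G")
  ifelse(purine(ref) == purine(alt), "transition", "transversion")
}

#' Assign minor-allele-frequency tranches
#'
#' Bins a MAF into the percent tranches used for accuracy stratification:
#' (0,1], (1,2], (2,5], (5,10], (10,20], (20,50]. Intervals are left-open and
#' right-closed, so a MAF of exactly 5% falls in (2,5]. A MAF of 0 is labelled
#' `"monomorphic"` and is excluded from tranche statistics downstream.
#'
#' @param maf numeric vector in `[0, 0.5]`.
#' @param edges tranche edges as frequencies; defaults to the standard set.
#' @return Factor with tranche labels plus `"monomorphic"`.
#' @export
maf_tranche <- function(maf, edges = c(0, 0.01, 0.02, 0.05, 0.10, 0.20, 0.50)) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  labs <- paste0("(", edges[-length(edges)] * 100, ",", edges[-1] * 100, "]")
  out <- as.character(cut(maf, breaks = edges, labels = labs, right = TRUE))
  out[!is.na(maf) & maf == 0] <- "monomorphic"
  factor(out, levels = c("monomorphic", labs))
}
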