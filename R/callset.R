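#' Construct a per-sample callset
#'
#' A callset pairs one sample's genotype dosages (0 = hom-ref, 1 = het,
#' 2 = hom-alt, `NA` = missing) with a shared site table, optionally carrying
#' the genotype-probability (GP) triple emitted by an imputation model.
#'
#' @param sample_id sample label.
#' @param sites site table from [new_sites()].
#' @param dosage integer vector aligned to `sites`; values 0/1/2 or `NA`.
#' @param gp optional numeric matrix `nrow(sites) x 3` of
#'   (P hom-ref, P het, P hom-alt); rows must sum to 1 within 1e-6 where the
#'   triple is present (a row of `NA` marks an absent triple).
#' @return An object of class `callset`.
#' @export
new_callset <- function(sample_id, sites, dosage, gp = NULL) {
  dosage <- as.integer(dosage)
  if (length(dosage) != nrow(sites))
    stop("dosage length must equal the number of sites")
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)))
    stop("dosage values must be 0, 1, 2 or NA")
  if (!is.null(gp)) {
    gp <- as.matrix(gp)
    if (nrow(gp) != nrow(sites) || ncol(gp) != 3)
      stop("gp must be an n_sites x 3 matrix")
    have <- !is.na(gp[, 1])
    if (any(have)) {
      if (any(gp[have, ] < 0)) stop("gp entries must be >= 0")
      if (any(abs(rowSums(gp[have, , drop = FALSE]) - 1) > 1e-6))
        stop("gp rows must sum to 1 within 1e-6")
    }
  }
  structure(list(sample_id = sample_id, sites = sites,
                 dosage = dosage, gp = gp),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  n <- length(x$dosage)
  cat(sprintf("callset '%s': %d sites, %d called (%.1f%%)%s\n",
              x$sample_id, n, sum(!is.na(x$dosage)),
              100 * mean(!is.na(x$dosage)),
              if (is.null(x$gp)) "" else ", with GP"))
  invisible(x)
}

#' Filter a callset on genotype probability
#'
#' Applies a maximum-GP quality filter: a call is kept only if the largest
#' entry of its GP triple reaches `threshold` *and* the recorded dosage equals
#' the argmax of the triple (an imputation model emits the argmax genotype, so
#' a mismatch marks an inconsistent record). Everything else, including calls
#' without a GP triple, is set to missing. The filter is idempotent.
#'
#' @param callset a [new_callset()] object with GP.
#' @param threshold minimum max-GP in (0, 1]; the conventional ladder is
#'   0.7, 0.8, 0.9, 0.95, 0.99. Boundary is inclusive (max-GP == threshold
#'   passes). `threshold = 0` is a no-op.
#' @return The callset with failing calls set to `NA`.
#' @export
apply_gp_filter <- function(callset, threshold) {
  stopifnot(inherits(callset, "callset"), threshold >= 0, threshold <= 1)
  if (threshold == 0) return(callset)
  d <- callset$dosage
  if (is.null(callset$gp)) {
    callset$dosage <- rep(NA_integer_, length(d))
    return(callset)
  }
  gp <- callset$gp
  gpmax <- do.call(pmax, c(as.data.frame(gp), na.rm = FALSE))
  argmax <- max.col(gp, ties.method = "first") - 1L
  keep <- !is.na(d) & !is.na(gpmax) & gpmax >= threshold & argmax == d
  callset$dosage[!keep] <- NA_integer_
  callset
}

#' Restrict callsets to a subset of site rows
#'
#' Internal helper: subsets the site table and every aligned vector/matrix.
#' @noRd
subset_callset <- function(callset, idx) {
  callset$sites <- callset$sites[idx, , drop = FALSE]
  rownames(callset$sites) <- NULL
  callset$dosage <- callset$dosage[idx]
  if (!is.null(callset$gp)) callset$gp <- callset$gp[idx, , drop = FALSE]
  callset
}

#' Check two callsets share one site list
#' @noRd
assert_same_sites <- function(a, b) {
  if (nrow(a$sites) != nrow(b$sites) ||
      !identical(a$sites$chrom, b$sites$chrom) ||
      !identical(a$sites$pos, b$sites$pos))
    stop("callsets do not share a common site list")
  invisible(TRUE)
}
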