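#' Read a VCF into a site table and callsets
#'
#' Reads GT (required) and GP (optional) FORMAT fields from a VCF 4.x file.
#' Only biallelic SNP records are used; multiallelic records and indels are
#' skipped with a message giving the count. Panel minor-allele frequency is
#' taken from the `PMAF` INFO key when present, otherwise computed from the
#' samples in the file. VCF positions (1-based) are converted to the package's
#' 0-based convention on read.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return A list with elements `sites` (site table) and `callsets` (list of
#'   [new_callset()] objects, one per VCF sample).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)

  chrom <- fix[biallelic, "CHROM"]
  pos1 <- as.numeric(fix[biallelic, "POS"])
  for (ch in unique(chrom)) {
    if (is.unsorted(pos1[chrom == ch], strictly = TRUE))
      stop("VCF records not sorted/unique within chromosome ", ch)
  }

  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if (!"GT" %in% fmt_keys) stop("VCF has no GT FORMAT field")
  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  dosage_of <- function(g) {
    g <- gsub("\\|", "/", g)
    d <- rep(NA_integer_, length(g))
    d[g %in% c("0/0")] <- 0L
    d[g %in% c("0/1", "1/0")] <- 1L
    d[g %in% c("1/1")] <- 2L
    d
  }

  gp_all <- NULL
  if ("GP" %in% fmt_keys) {
    gp_raw <- vcfR::extract.gt(vcf, element = "GP")[biallelic, , drop = FALSE]
    gp_all <- lapply(seq_len(ncol(gp_raw)), function(j) {
      parts <- strsplit(gp_raw[, j], ",")
      m <- t(vapply(parts, function(p) {
        if (length(p) == 3) as.numeric(p) else rep(NA_real_, 3)
      }, numeric(3)))
      # renormalize away the rounding error of fixed-precision GP text
      rs <- rowSums(m)
      ok <- !is.na(rs) & rs > 0
      m[ok, ] <- m[ok, , drop = FALSE] / rs[ok]
      m
    })
  }

  # panel MAF: INFO PMAF if present, else from sample allele counts
  info <- fix[biallelic, "INFO"]
  pmaf <- suppressWarnings(as.numeric(sub(".*(?:^|;)PMAF=([^;]+).*", "\\1",
                                          info, perl = TRUE)))
  pmaf[!grepl("PMAF=", info)] <- NA_real_
  if (anyNA(pmaf)) {
    dmat <- vapply(seq_len(ncol(gt)), function(j) dosage_of(gt[, j]),
                   integer(nrow(gt)))
    dmat <- matrix(dmat, nrow = nrow(gt))
    ac <- rowSums(dmat, na.rm = TRUE)
    an <- 2 * rowSums(!is.na(dmat))
    f <- ifelse(an > 0, ac / an, 0)
    pmaf[is.na(pmaf)] <- pmin(f, 1 - f)[is.na(pmaf)]
  }

  sites <- new_sites(chrom, pos1 - 1, ref[biallelic], alt[biallelic], pmaf)
  # new_sites sorts; establish the mapping from file order to sorted order
  ord <- order(chrom, pos1 - 1)

  callsets <- lapply(seq_len(ncol(gt)), function(j) {
    d <- dosage_of(gt[, j])[ord]
    gpj <- if (!is.null(gp_all)) gp_all[[j]][ord, , drop = FALSE] else NULL
    new_callset(colnames(gt)[j], sites, d, gpj)
  })
  names(callsets) <- colnames(gt)
  list(sites = sites, callsets = callsets, n_skipped = n_skipped)
}

#' Write callsets to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT (and GP when any callset carries it),
#' the panel MAF as INFO key `PMAF`, and missing genotypes as `./.`.
#' All callsets must share one site table. Internal 0-based positions are
#' written 1-based.
#'
#' @param sites site table shared by `callsets`.
#' @param callsets list of [new_callset()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, callsets, path) {
  for (cs in callsets) {
    if (!identical(cs$sites$chrom, sites$chrom) ||
        !identical(cs$sites$pos, sites$pos))
      stop("all callsets must share the given site table")
  }
  has_gp <- any(vapply(callsets, function(cs) !is.null(cs$gp), logical(1)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##INFO=<ID=PMAF,Number=1,Type=Float,Description=\"Panel minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_gp)
      "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior probabilities\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vapply(callsets, function(cs) cs$sample_id,
                             character(1))),
          collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  cols <- lapply(callsets, function(cs) {
    g <- ifelse(is.na(cs$dosage), "./.", gt_str[cs$dosage + 1L])
    if (has_gp) {
      if (is.null(cs$gp)) {
        g <- paste0(g, ":.")
      } else {
        gp_txt <- apply(cs$gp, 1, function(p) {
          if (anyNA(p)) "." else paste(formatC(p, format = "f", digits = 4),
                                       collapse = ",")
        })
        g <- paste0(g, ":", gp_txt)
      }
    }
    g
  })
  fixed_cols <- list(
    sites$chrom, format(sites$pos + 1, scientific = FALSE, trim = TRUE),
    ".", sites$ref, sites$alt, ".", ".",
    paste0("PMAF=", formatC(sites$maf, format = "g", digits = 6)))
  if (length(callsets) > 0)
    fixed_cols <- c(fixed_cols, list(if (has_gp) "GT:GP" else "GT"))
  body <- if (length(callsets) == 0 && nrow(sites) == 0) character(0) else
    do.call(paste, c(fixed_cols, cols, list(sep = "\t")))
  if (length(callsets) == 0) {
    hdr[length(hdr)] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                "FILTER", "INFO"), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
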