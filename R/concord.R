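#' Cross-tabulate truth against imputed genotypes
#'
#' Builds the confusion counts underlying all accuracy metrics: truth dosage
#' (0/1/2) against imputed dosage (0/1/2/miss), optionally stratified by MAF
#' tranche and substitution class. Imputed calls failing the GP filter are
#' counted in the imputed-`miss` column; sites where the truth is missing are
#' excluded (they can contribute to no rate). Counts partition the compared
#' sites exactly.
#'
#' @param truth,imputed [new_callset()] objects sharing one site table.
#' @param gp_threshold max-GP filter applied to `imputed` (0 = no filter).
#' @param by_tranche,by_subst_class include the stratification column(s).
#' @return data.frame with columns (`tranche`,) (`subst_class`,) `truth`,
#'   `imputed`, `n`; class `confusion_counts`.
#' @export
crosstab <- function(truth, imputed, gp_threshold = 0,
                     by_tranche = TRUE, by_subst_class = TRUE) {
  assert_same_sites(truth, imputed)
  if (gp_threshold > 0 && is.null(imputed$gp))
    stop("gp_threshold > 0 requires the imputed callset to carry GP")
  imputed <- apply_gp_filter(imputed, gp_threshold)
  keep <- !is.na(truth$dosage)
  t_d <- factor(truth$dosage[keep], levels = 0:2)
  i_d <- factor(ifelse(is.na(imputed$dosage[keep]), "miss",
                       as.character(imputed$dosage[keep])),
                levels = c("0", "1", "2", "miss"))
  strata <- list()
  if (by_tranche)
    strata$tranche <- droplevels(maf_tranche(truth$sites$maf[keep]))
  if (by_subst_class)
    strata$subst_class <- factor(truth$sites$subst_class[keep])
  tab <- as.data.frame(table(c(strata, list(truth = t_d, imputed = i_d))),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  class(tab) <- c("confusion_counts", "data.frame")
  tab
}

# sum of counts for given truth/imputed cells
cnt <- function(counts, truth, imputed) {
  sum(counts$n[counts$truth %in% truth & counts$imputed %in% imputed])
}

#' Non-reference concordance
#'
#' Fraction of truth heterozygous and homozygous-alternative genotypes that
#' the imputed callset recovers exactly:
#' `(n[1->1] + n[2->2]) / n[truth in {1,2}, imputed in {0,1,2}]`. The
#' denominator is conditional on an imputed call being made — sites whose
#' imputed call is missing after GP filtering are excluded. Set
#' `conditional = FALSE` to count them in the denominator instead.
#'
#' @param counts a [crosstab()] result (any stratum subset; rows are summed).
#' @param conditional exclude imputed-missing sites from the denominator.
#' @return Rate in `[0,1]`, or `NA` when the denominator is empty.
#' @export
nonref_concordance <- function(counts, conditional = TRUE) {
  num <- cnt(counts, "1", "1") + cnt(counts, "2", "2")
  den_cols <- if (conditional) c("0", "1", "2") else c("0", "1", "2", "miss")
  den <- cnt(counts, c("1", "2"), den_cols)
  if (den == 0) NA_real_ else num / den
}

#' Heterozygous false-positive rate
#'
#' `FP / (FP + TN)` where FP counts truth-homozygous sites imputed as
#' heterozygous and TN counts truth-homozygous sites imputed as the *same*
#' homozygote (cross-homozygote errors belong to neither term).
#'
#' @inheritParams nonref_concordance
#' @return Rate in `[0,1]`, or `NA` when `FP + TN = 0`.
#' @export
het_fpr <- function(counts) {
  fp <- cnt(counts, "0", "1") + cnt(counts, "2", "1")
  tn <- cnt(counts, "0", "0") + cnt(counts, "2", "2")
  if (fp + tn == 0) NA_real_ else fp / (fp + tn)
}

#' Heterozygous false-negative rate
#'
#' Fraction of truth heterozygotes imputed as homozygous, among truth
#' heterozygotes with a non-missing imputed call.
#'
#' @inheritParams nonref_concordance
#' @return Rate in `[0,1]`, or `NA` when no truth het has a call.
#' @export
het_fnr <- function(counts) {
  wrong <- cnt(counts, "1", "0") + cnt(counts, "1", "2")
  den <- wrong + cnt(counts, "1", "1")
  if (den == 0) NA_real_ else wrong / den
}

#' Tidy accuracy table over GP thresholds and strata
#'
#' Convenience wrapper running [crosstab()] at each GP threshold and
#' computing all three rates per (tranche, substitution class) stratum plus
#' the pooled stratum, in long format.
#'
#' @inheritParams crosstab
#' @param gp_thresholds numeric vector of max-GP filters.
#' @return data.frame with columns `sample`, `gp`, `tranche`, `subst_class`,
#'   `metric`, `value`, `n` (`n` = compared sites in the stratum with a
#'   non-missing imputed call).
#' @export
concordance_table <- function(truth, imputed,
                              gp_thresholds = c(0.7, 0.8, 0.9, 0.95, 0.99),
                              by_tranche = TRUE, by_subst_class = TRUE) {
  out <- list()
  for (g in gp_thresholds) {
    tab <- crosstab(truth, imputed, g, by_tranche, by_subst_class)
    tr_lev <- if (by_tranche) c("all", as.character(unique(tab$tranche)))
              else "all"
    cl_lev <- if (by_subst_class) c("all", as.character(unique(tab$subst_class)))
              else "all"
    for (tr in tr_lev) for (cl in cl_lev) {
      sub <- tab
      if (tr != "all") sub <- sub[as.character(sub$tranche) == tr, ]
      if (cl != "all") sub <- sub[as.character(sub$subst_class) == cl, ]
      n_called <- cnt(sub, c("0", "1", "2"), c("0", "1", "2"))
      for (m in c("nonref_concordance", "het_fpr", "het_fnr")) {
        v <- switch(m, nonref_concordance = nonref_concordance(sub),
                    het_fpr = het_fpr(sub), het_fnr = het_fnr(sub))
        out[[length(out) + 1]] <- data.frame(
          sample = truth$sample_id, gp = g, tranche = tr, subst_class = cl,
          metric = m, value = v, n = n_called, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Site-recovery accounting: imputed versus pseudohaploid
#'
#' Counts, per sample and restricted to sites with `maf >= maf_min`, how many
#' sites carry a non-missing call in the (GP-filtered) imputed data and in the
#' pseudohaploid data, and how many imputed calls are non-reference (split
#' heterozygous vs homozygous-alternative).
#'
#' @param imputed_filtered GP-filtered imputed callset.
#' @param pseudohaploid pseudohaploid callset on the same sites.
#' @param maf_min inclusive panel-MAF threshold (e.g. 0.05).
#' @return One-row data.frame: `sample`, `n_sites`, `n_imputed`, `n_pseudo`,
#'   `n_nonref`, `n_het`, `n_homalt`.
#' @export
recovery_table <- function(imputed_filtered, pseudohaploid, maf_min = 0) {
  assert_same_sites(imputed_filtered, pseudohaploid)
  keep <- imputed_filtered$sites$maf >= maf_min
  di <- imputed_filtered$dosage[keep]
  dp <- pseudohaploid$dosage[keep]
  data.frame(
    sample = imputed_filtered$sample_id,
    n_sites = sum(keep),
    n_imputed = sum(!is.na(di)),
    n_pseudo = sum(!is.na(dp)),
    n_nonref = sum(di %in% c(1L, 2L)),
    n_het = sum(di == 1L, na.rm = TRUE),
    n_homalt = sum(di == 2L, na.rm = TRUE),
    stringsAsFactors = FALSE)
}
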