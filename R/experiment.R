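#' End-to-end synthetic downsampling experiment
#'
#' Reproduces the structure of a coverage-ladder imputation experiment on
#' synthetic data: simulate a haplotype panel and truth diploids once, then
#' for every coverage in the ladder generate an imputed callset under the
#' error model and tabulate non-reference concordance, heterozygous FPR and
#' FNR at every GP threshold, MAF tranche and substitution class. The
#' result is one tidy table with the coverage x GP x tranche x class x
#' metric axes.
#'
#' @param panel_cfg a [panel_config()].
#' @param model an [error_model()].
#' @param coverages coverage ladder in x-fold (default 0.1 to 4).
#' @param gp_thresholds max-GP filter ladder.
#' @param n_individuals truth individuals to simulate.
#' @param seed integer seed controlling every stage.
#' @return data.frame with columns `sample`, `coverage`, `gp`, `tranche`,
#'   `subst_class`, `metric`, `value`, `n`; `n` is the metric's own
#'   denominator in the stratum (non-reference called sites for
#'   concordance, FP+TN for the FPR, called truth heterozygotes for the
#'   FNR), so each rate's binomial noise can be judged per row. Every
#'   combination of the axes appears exactly once per sample (value `NA`,
#'   `n` 0 where a stratum is empty).
#' @export
run_experiment <- function(panel_cfg = panel_config(),
                           model = error_model(),
                           coverages = c(0.1, 0.25, 0.5, 0.75, 1, 2, 4),
                           gp_thresholds = c(0.7, 0.8, 0.9, 0.95, 0.99),
                           n_individuals = 2, seed = 1L) {
  panel <- simulate_panel(panel_cfg)
  truth <- simulate_truth(panel, n_individuals, seed = seed + 1L)
  tranche_levels <- levels(maf_tranche(0.1))
  tranche_levels <- setdiff(tranche_levels, "monomorphic")
  class_levels <- c("transition", "transversion")
  metrics <- c("nonref_concordance", "het_fpr", "het_fnr")
  out <- list()
  for (ci in seq_along(coverages)) {
    cov <- coverages[ci]
    for (si in seq_len(n_individuals)) {
      imp <- simulate_imputed(truth$callsets[[si]], model, cov,
                              seed = seed + 100L * ci + si)
      for (g in gp_thresholds) {
        tab <- crosstab(truth$callsets[[si]], imp, g)
        for (tr in tranche_levels) for (cl in class_levels) {
          sub <- tab[as.character(tab$tranche) == tr &
                       as.character(tab$subst_class) == cl, , drop = FALSE]
          vals <- c(nonref_concordance(sub), het_fpr(sub), het_fnr(sub))
          # n is each rate's own denominator, so noise can be judged per row
          ns <- c(cnt(sub, c("1", "2"), c("0", "1", "2")),
                  cnt(sub, c("0", "2"), "1") + cnt(sub, "0", "0") +
                    cnt(sub, "2", "2"),
                  cnt(sub, "1", c("0", "1", "2")))
          out[[length(out) + 1]] <- data.frame(
            sample = truth$callsets[[si]]$sample_id, coverage = cov,
            gp = g, tranche = tr, subst_class = cl, metric = metrics,
            value = vals, n = ns, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a complete synthetic dataset to disk
#'
#' Generates a panel, truth diploids with planted ROH and IBD segments, an
#' imputed and a pseudohaploid callset per coverage, noisy IBD tables, and
#' writes everything in the package's text formats (VCF, genetic-map text,
#' RefinedIBD-style tables, a TSV manifest of planted segments). Every
#' output is reproducible from the seed.
#'
#' @param dir output directory (created if needed).
#' @param panel_cfg a [panel_config()].
#' @param model an [error_model()].
#' @param coverages coverage ladder.
#' @param n_individuals truth individuals.
#' @param roh_plan,ibd_plan planted-segment plans (see [simulate_truth()]).
#' @param seed integer seed.
#' @return Invisibly, a list of the generated in-memory objects.
#' @export
simulate_dataset <- function(dir, panel_cfg = panel_config(),
                             model = error_model(),
                             coverages = 0.5, n_individuals = 2,
                             roh_plan = NULL, ibd_plan = NULL, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(panel_cfg)
  truth <- simulate_truth(panel, n_individuals, roh_plan, ibd_plan,
                          seed = seed + 1L)
  write_vcf(panel$sites, truth$callsets, file.path(dir, "truth.vcf"))
  write_map(panel$map, file.path(dir, "map.txt"))
  utils::write.table(truth$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  imputed <- list(); pseudo <- list()
  for (ci in seq_along(coverages)) {
    cov <- coverages[ci]
    imp <- lapply(seq_len(n_individuals), function(si)
      simulate_imputed(truth$callsets[[si]], model, cov,
                       seed = seed + 100L * ci + si))
    ps <- lapply(seq_len(n_individuals), function(si)
      pseudohaploidize(truth$callsets[[si]], cov,
                       seed = seed + 1000L * ci + si))
    tag <- gsub("\\.", "p", format(cov))
    write_vcf(panel$sites, imp, file.path(dir, paste0("imputed_", tag,
                                                      "x.vcf")))
    write_vcf(panel$sites, ps, file.path(dir, paste0("pseudo_", tag,
                                                     "x.vcf")))
    imputed[[ci]] <- imp; pseudo[[ci]] <- ps
  }
  ibd_runs <- NULL
  if (!is.null(ibd_plan)) {
    ibd_runs <- emit_ibd_tables(truth$manifest, panel$map,
                                samples = names(truth$callsets),
                                seed = seed + 7L)
    for (r in seq_along(ibd_runs))
      write_ibd_table(ibd_runs[[r]],
                      file.path(dir, sprintf("ibd_run%d.tsv", r)))
  }
  invisible(list(panel = panel, truth = truth, imputed = imputed,
                 pseudo = pseudo, ibd_runs = ibd_runs))
}
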