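test_that("zero switch rate copies founders verbatim; founders-only panel", {
  cfg <- panel_config(n_founders = 5, n_haplotypes = 12, n_sites = 400,
                      chrom_lengths = c("1" = 1e6), switch_rate_per_cM = 0,
                      seed = 1)
  p <- simulate_panel(cfg)
  founders <- p$haplotypes[1:5, , drop = FALSE]
  for (h in 6:12) {
    match_any <- any(apply(founders, 1, function(f)
      all(f == p$haplotypes[h, ])))
    expect_true(match_any)
  }
  cfg2 <- panel_config(n_founders = 6, n_haplotypes = 6, n_sites = 300,
                       chrom_lengths = c("1" = 1e6), seed = 2)
  p2 <- simulate_panel(cfg2)
  expect_equal(nrow(p2$haplotypes), 6)
})

test_that("U-shaped founder frequencies give an excess of rare alleles", {
  cfg <- panel_config(n_founders = 40, n_haplotypes = 200, n_sites = 20000,
                      chrom_lengths = c("1" = 4e7),
                      founder_freq_alpha = 0.3, founder_freq_beta = 0.3,
                      seed = 3)
  p <- simulate_panel(cfg)
  poly <- p$sites$maf[p$sites$maf > 0]
  expect_gt(mean(poly < 0.05), mean(poly > 0.45 & poly <= 0.5))
})

test_that("generators are reproducible under a fixed seed", {
  cfg <- panel_config(n_founders = 8, n_haplotypes = 20, n_sites = 500,
                      chrom_lengths = c("1" = 1e6), seed = 11)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  p <- simulate_panel(cfg)
  t1 <- simulate_truth(p, 2, seed = 5)
  t2 <- simulate_truth(p, 2, seed = 5)
  expect_identical(t1$callsets, t2$callsets)
  i1 <- simulate_imputed(t1$callsets[[1]], error_model(), 0.5, seed = 6)
  i2 <- simulate_imputed(t1$callsets[[1]], error_model(), 0.5, seed = 6)
  expect_identical(i1, i2)
  expect_identical(pseudohaploidize(t1$callsets[[1]], 0.5, seed = 7),
                   pseudohaploidize(t1$callsets[[1]], 0.5, seed = 7))
})

test_that("planted ROH tracts are exactly homozygous; IBD pairs share a haplotype", {
  panel <- small_panel()
  roh <- data.frame(sample = 1, chrom = "1", start = 2e6, end = 8e6)
  ibd <- data.frame(sample_a = 2, sample_b = 3, chrom = "1",
                    start = 1e6, end = 6e6)
  tr <- simulate_truth(panel, 3, roh_plan = roh, ibd_plan = ibd, seed = 8)
  sites <- panel$sites
  inside <- sites$pos >= 2e6 & sites$pos < 8e6
  expect_true(all(tr$callsets[[1]]$dosage[inside] %in% c(0L, 2L)))
  outside_het <- sum(tr$callsets[[1]]$dosage[!inside] == 1L)
  expect_gt(outside_het, 0)
  # IBD pair: identical first haplotype across the planted tract
  sel <- sites$pos >= 1e6 & sites$pos < 6e6
  expect_identical(tr$haplotypes[[2]][1, sel], tr$haplotypes[[3]][1, sel])
  # full-genome ROH kills heterozygosity entirely
  tr2 <- simulate_truth(panel, 1,
                        roh_plan = data.frame(sample = 1, chrom = "1",
                                              start = 0, end = 1e7),
                        seed = 9)
  expect_false(any(tr2$callsets[[1]]$dosage == 1L, na.rm = TRUE))
  # overlapping ROH plans are refused
  expect_error(simulate_truth(panel, 1, roh_plan = data.frame(
    sample = c(1, 1), chrom = "1", start = c(0, 5e5), end = c(1e6, 2e6))),
    "overlap")
})

test_that("error model degenerate limits: zero error and total error", {
  panel <- small_panel()
  truth <- simulate_truth(panel, 1, seed = 10)
  zero <- error_model(p_wrong = default_p_wrong() * 0, miss_rate = 0)
  imp0 <- simulate_imputed(truth$callsets[[1]], zero, 0.5, seed = 11)
  expect_identical(imp0$dosage, truth$callsets[[1]]$dosage)
  expect_equal(nonref_concordance(crosstab(truth$callsets[[1]], imp0, 0)), 1)
  all_wrong <- error_model(p_wrong = (default_p_wrong() * 0) + 1,
                           coverage_decay = 0)
  imp1 <- simulate_imputed(truth$callsets[[1]], all_wrong, 0.5, seed = 12)
  expect_equal(nonref_concordance(crosstab(truth$callsets[[1]], imp1, 0)), 0)
})

test_that("GP triples are argmax-consistent and calibration is monotone in GP", {
  panel <- small_panel(n_sites = 20000, chrom_lengths = c("1" = 4e7))
  truth <- simulate_truth(panel, 1, seed = 13)
  imp <- simulate_imputed(truth$callsets[[1]], error_model(), 0.5, seed = 14)
  ok <- !is.na(imp$dosage)
  expect_true(all(abs(rowSums(imp$gp[ok, ]) - 1) < 1e-9))
  expect_equal(max.col(imp$gp[ok, ]) - 1L, imp$dosage[ok])
  conc <- vapply(c(0, 0.7, 0.8, 0.9, 0.95, 0.99), function(g)
    nonref_concordance(crosstab(truth$callsets[[1]], imp, g)), numeric(1))
  # non-decreasing up to one small noise inversion
  expect_true(all(diff(conc) >= -0.002))
})

test_that("pseudohaploid calls follow Poisson missingness and fair allele draws", {
  d <- rep(1L, 10000)
  cs <- make_callset(d)
  ps <- pseudohaploidize(cs, 0.5, seed = 15)
  miss <- mean(is.na(ps$dosage))
  se <- sqrt(exp(-0.5) * (1 - exp(-0.5)) / 10000)
  expect_lt(abs(miss - exp(-0.5)), 3 * se)
  called <- ps$dosage[!is.na(ps$dosage)]
  expect_true(all(called %in% c(0L, 2L)))
  chi <- chisq.test(table(factor(called, levels = c(0, 2))))
  expect_gt(chi$p.value, 0.01)
  # homozygous truth always recovers the true allele when covered
  cs2 <- make_callset(rep(c(0L, 2L), 500))
  ps2 <- pseudohaploidize(cs2, 5, seed = 16)
  ok <- !is.na(ps2$dosage)
  expect_identical(ps2$dosage[ok], cs2$dosage[ok])
})

test_that("emitted IBD tables reconstruct planted tracts and only decoys fail filters", {
  panel <- small_panel(n_sites = 3000, chrom_lengths = c("1" = 3e7))
  ibd <- data.frame(sample_a = c(1, 1), sample_b = c(2, 3), chrom = "1",
                    start = c(2e6, 1.5e7), end = c(1e7, 2.4e7))
  tr <- simulate_truth(panel, 4, ibd_plan = ibd, seed = 17)
  runs <- emit_ibd_tables(tr$manifest, panel$map,
                          samples = names(tr$callsets), n_runs = 3,
                          split_prob = 0, seed = 18)
  # split_prob 0: one emitted segment per planted tract per run (+ decoys)
  for (r in runs) {
    true_rows <- r[paste(r$sample_a, r$sample_b) %in%
                     c("ind01 ind02", "ind01 ind03"), ]
    expect_equal(nrow(true_rows), 2)
  }
  # with splitting, downstream merge reconstitutes each tract within jitter
  runs2 <- emit_ibd_tables(tr$manifest, panel$map,
                           samples = names(tr$callsets), n_runs = 3,
                           split_prob = 0.5, seed = 19)
  comb <- combine_runs(runs2, panel$map, exclude = NULL)
  merged <- merge_pair_segments(comb, 0.6, map = panel$map)
  for (i in seq_len(nrow(ibd))) {
    pa <- sprintf("ind%02d", ibd$sample_a[i])
    pb <- sprintf("ind%02d", ibd$sample_b[i])
    seg <- merged[merged$sample_a == pa & merged$sample_b == pb, ]
    planted_cm <- interpolate_cm(panel$map, "1", ibd$end[i]) -
      interpolate_cm(panel$map, "1", ibd$start[i])
    expect_lt(abs(sum(seg$length_cm) - planted_cm), 0.6 + 2 * 0.2)
  }
  # decoys never classify a non-planted pair as related
  cls <- classify_all_pairs(merged)
  rel_pairs <- cls[cls$related, c("sample_a", "sample_b")]
  expect_true(all(paste(rel_pairs$sample_a, rel_pairs$sample_b) %in%
                    c("ind01 ind02", "ind01 ind03")))
})
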