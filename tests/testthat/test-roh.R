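test_that("window-scan caller handles canonical homozygous runs", {
  # 300 hom SNPs spanning ~600 kb with clean heterozygous flanks
  d <- c(rep(c(0L, 1L), 30), rep(0L, 300), rep(c(1L, 0L), 30))
  pos <- c(seq(0, by = 3000, length.out = 60),
           seq(200000, by = 2000, length.out = 300),
           seq(900000, by = 3000, length.out = 60))
  sites <- new_sites(rep("1", length(d)), pos, "A", "C", 0.2)
  cs <- new_callset("s", sites, d)
  segs <- windowscan_roh(cs, windowscan_params(min_snp = 200))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 300)
  expect_gte(segs$length_bp, 500000)
  expect_equal(segs$length_bp, segs$end - segs$start)
  # 199 SNPs with min_snp 200 fails the count filter
  d2 <- c(rep(1L, 10), rep(0L, 199), rep(1L, 10))
  cs2 <- make_callset(d2, spacing = 3000)
  expect_equal(nrow(windowscan_roh(cs2, windowscan_params(min_snp = 200))), 0)
  # an all-heterozygous callset yields nothing
  expect_equal(nrow(windowscan_roh(make_callset(rep(1L, 400)),
                                   windowscan_params())), 0)
  # chromosome shorter than one window yields nothing
  expect_equal(nrow(windowscan_roh(make_callset(rep(0L, 30)),
                                   windowscan_params())), 0)
})

test_that("window-scan caller matches the brute-force oracle on random instances", {
  set.seed(41)
  for (rep in 1:150) {
    n <- sample(60:400, 1)
    p_het <- runif(1, 0.02, 0.4)
    d <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2, 0.05))
    pos <- sort(sample.int(n * 3000, n)) - 1
    params <- windowscan_params(
      window_snp = sample(10:30, 1), window_het = sample(0:2, 1),
      window_missing = sample(1:5, 1),
      window_threshold = runif(1, 0.02, 0.3),
      min_snp = sample(10:40, 1), min_kb = sample(c(20, 50, 100), 1),
      max_gap_kb = sample(c(20, 50, 100), 1))
    cs <- new_callset("s", new_sites(rep("1", n), pos, "A", "C", 0.2), d)
    got <- windowscan_roh(cs, params)
    want <- brute_windowscan(d, pos, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("HMM caller recovers a clean autozygous run and degenerate limits", {
  d <- c(rep(1L, 100), rep(0L, 600), rep(1L, 100))
  cs <- make_callset(d, spacing = 1000, maf = 0.4)
  segs <- hmm_roh(cs, site_freqs = rep(0.4, 800),
                  params = hmm_params(min_snp = 200))
  expect_equal(nrow(segs), 1)
  expect_gt(segs$quality, 10)
  expect_gte(segs$start, 99 * 1000)
  expect_lte(segs$end, 701000)
  # alternating het/hom never passes the filters
  alt <- make_callset(rep(c(0L, 1L), 350), maf = 0.4)
  expect_equal(nrow(hmm_roh(alt, rep(0.4, 700),
                            hmm_params(min_snp = 200))), 0)
  # uninformative emissions (e -> 0.5): the genotype data cannot matter,
  # so the called profile follows the transition prior alone and is
  # identical for all-homozygous and all-heterozygous input
  uninf <- hmm_params(err_phred = 10 * log10(2), min_snp = 200)
  hom_in <- hmm_roh(make_callset(rep(0L, 700), maf = 0.4),
                    rep(0.4, 700), uninf)
  het_in <- hmm_roh(make_callset(rep(1L, 700), maf = 0.4),
                    rep(0.4, 700), uninf)
  expect_equal(hom_in[, c("start", "end", "n_snps")],
               het_in[, c("start", "end", "n_snps")])
})

test_that("Viterbi equals exhaustive path search; posteriors sum to one", {
  set.seed(43)
  for (rep in 1:60) {
    L <- sample(2:12, 1)
    pos <- sort(sample.int(5e6, L)) - 1
    het <- runif(L) < 0.4
    p <- runif(L, 0.05, 0.95)
    params <- hmm_params(err_phred = runif(1, 10, 40),
                         t_hw2az = 10^runif(1, -9, -6),
                         t_az2hw = 10^runif(1, -10, -7))
    model <- hmm_model(pos, het, p, params)
    vit <- hmm_viterbi(model)
    brute <- brute_best_path(model)
    expect_equal(vit$logp, brute$logp, tolerance = 1e-9)
    post <- hmm_posterior(model)
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("ROH fusion applies the strict 4 Mb rule and mergeBed accounting", {
  ws <- data.frame(sample = "s", chrom = "1", start = 1e6, end = 2e6,
                   n_snps = 300L, length_bp = 1e6, source = "windowscan",
                   stringsAsFactors = FALSE)
  hmm <- data.frame(sample = "s", chrom = "1", start = 1.5e6, end = 6e6,
                    n_snps = 900L, length_bp = 4.5e6, source = "hmm",
                    quality = 60, stringsAsFactors = FALSE)
  fused <- fuse_roh(ws, hmm)
  expect_equal(nrow(fused), 1)
  expect_equal(c(fused$start, fused$end), c(1e6, 6e6))
  expect_equal(fused$n_sources, 2)
  expect_equal(fused$collapsed_lengths, "1000000,4500000")
  # 3.9 Mb HMM segment is excluded by the strict > 4e6 rule
  hmm_short <- transform(hmm, end = start + 3.9e6, length_bp = 3.9e6)
  fused2 <- fuse_roh(ws, hmm_short)
  expect_equal(nrow(fused2), 1)
  expect_equal(fused2$end, 2e6)
  expect_equal(fused2$n_sources, 1)
  # disjoint inputs pass through with count 1 each
  hmm_far <- transform(hmm, start = 2e7, end = 2e7 + 4.5e6)
  fused3 <- fuse_roh(ws, hmm_far)
  expect_equal(nrow(fused3), 2)
  expect_equal(fused3$n_sources, c(1, 1))
  # fused intervals are disjoint/sorted; lengths bracketed by the inputs
  expect_true(all(diff(fused3$start) > 0))
  expect_gte(sum(fused$length_bp), sum(ws$length_bp))
  expect_lte(sum(fused$length_bp), sum(ws$length_bp) + sum(hmm$length_bp))
})

test_that("ROH length-bin summary partitions the total", {
  segs <- data.frame(length_bp = c(0.7e6, 1.5e6, 9e6))
  s <- roh_summary(segs)
  expect_equal(s$mb[s$bin == "(0.5,1]"], 0.7)
  expect_equal(s$mb[s$bin == "(1,2]"], 1.5)
  expect_equal(s$mb[s$bin == "(8,Inf]"], 9)
  expect_equal(attr(s, "total_mb"), 11.2)
  expect_equal(sum(s$mb), attr(s, "total_mb"))
  empty <- roh_summary(segs[0, , drop = FALSE])
  expect_true(all(empty$mb == 0))
  # under-bin flag for sub-threshold segments
  tiny <- roh_summary(data.frame(length_bp = 1e5))
  expect_true(isTRUE(attr(tiny, "under_bin_flag")))
})

test_that("site downsampling is reproducible and preserves order", {
  cs <- make_callset(sample(c(0L, 1L, 2L, NA), 500, replace = TRUE,
                            prob = c(0.4, 0.2, 0.3, 0.1)))
  a <- downsample_sites(cs, 200, seed = 44)
  b <- downsample_sites(cs, 200, seed = 44)
  expect_identical(a, b)
  expect_false(is.unsorted(a$sites$pos))
  expect_false(anyNA(a$dosage))
  n_nonmiss <- sum(!is.na(cs$dosage))
  full <- downsample_sites(cs, n_nonmiss, seed = 45)
  expect_identical(full$dosage, cs$dosage[!is.na(cs$dosage)])
  expect_error(downsample_sites(cs, n_nonmiss + 1), "exceeds")
})

test_that("exact Mann-Whitney p-values match enumeration and printed values", {
  # U = 7 with sizes (6, 8): 44/3003; U = 6 with (4, 8): 27/495
  c68 <- mwu_null_counts(6, 8)
  expect_equal(sum(c68), choose(14, 6))
  expect_equal(sum(c68[1:8]) / choose(14, 6), 44 / 3003)
  expect_equal(round(sum(c68[1:8]) / choose(14, 6), 5), 0.01465)
  c48 <- mwu_null_counts(4, 8)
  expect_equal(round(sum(c48[1:7]) / choose(12, 4), 5), 0.05455)
  # exhaustive enumeration oracle for a small case
  n <- 3; m <- 4
  vals <- seq_len(n + m)
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx)
    sum(outer(vals[idx], vals[-idx], "<")))
  want <- tabulate(u_all + 1, nbins = n * m + 1)
  expect_equal(mwu_null_counts(n, m), want)
  # symmetry P(U<=u | n,m) = P(U<=u | m,n) for all n+m <= 12
  for (n2 in 1:6) for (m2 in 1:(12 - n2)) {
    expect_equal(mwu_null_counts(n2, m2), mwu_null_counts(m2, n2))
    expect_equal(sum(mwu_null_counts(n2, m2)), choose(n2 + m2, n2))
  }
})

test_that("mwu_groups computes the directional U and refuses ties", {
  r <- mwu_groups(c(5, 6), c(1, 2, 3), tail = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / choose(5, 2))
  r2 <- mwu_groups(c(1), c(2), tail = "less")
  expect_equal(r2$U, 1)
  expect_equal(r2$p, 1)
  r3 <- mwu_groups(c(2), c(1), tail = "less")
  expect_equal(r3$U, 0)
  expect_equal(r3$p, 0.5)
  expect_error(mwu_groups(c(1, 2), c(2, 3)), "tie")
  expect_error(mwu_groups(numeric(0), c(1)), "non-empty")
  # agreement with base R's exact one-sided test on random data
  set.seed(46)
  for (rep in 1:10) {
    a <- runif(sample(3:6, 1)); b <- runif(sample(3:6, 1))
    got <- mwu_groups(a, b, tail = "greater")
    ref <- stats::wilcox.test(a, b, alternative = "less", exact = TRUE)
    expect_equal(got$p, ref$p.value)
  }
})
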