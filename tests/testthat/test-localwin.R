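test_that("make_windows follows the makewindows dialect", {
  w <- make_windows(c("1" = 1e6), size = 5e5, step = 1e5)
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(0, 9e5, 1e5))
  expect_equal(w$end[10], 1e6)
  expect_equal(w$end[6], 1e6)  # truncated
  # step == size tiles without overlap
  w2 <- make_windows(c("1" = 1e6), size = 2e5, step = 2e5)
  expect_equal(w2$start[-1], w2$end[-nrow(w2)])
  # chromosome shorter than the window: one truncated window
  w3 <- make_windows(c("1" = 3e5), size = 5e5, step = 1e5)
  expect_equal(nrow(w3), 3)
  expect_equal(w3$end, rep(3e5, 3))
  expect_equal(w3$start, c(0, 1e5, 2e5))
})

test_that("window rates aggregate sites into overlapping windows", {
  sites <- new_sites(rep("1", 100), seq(0, 990000, 10000),
                     rep("A", 100), rep("C", 100), rep(0.2, 100))
  wins <- make_windows(c("1" = 1e6), 5e5, 1e5)
  all_ok <- window_rates(sites, rep(TRUE, 100), rep(TRUE, 100), wins)
  expect_true(all(all_ok$rate[all_ok$n_total > 0] == 1))
  # non-overlapping windows: weighted mean equals the genome-wide rate
  set.seed(31)
  num <- runif(100) < 0.7
  tile <- make_windows(c("1" = 1e6), 1e5, 1e5)
  wr <- window_rates(sites, rep(TRUE, 100), num, tile)
  expect_equal(sum(wr$n_event) / sum(wr$n_total), mean(num))
  expect_equal(sum(wr$n_total), 100)
  # empty windows get NA rates
  gap_sites <- new_sites(rep("1", 10), seq(0, 9000, 1000),
                         rep("A", 10), rep("C", 10), rep(0.2, 10))
  wr2 <- window_rates(gap_sites, rep(TRUE, 10), rep(TRUE, 10), tile)
  expect_true(is.na(wr2$rate[5]))
})

test_that("percentile outliers use nearest-rank with tie inclusion and merging", {
  wins <- make_windows(c("1" = 1e7), 1e5, 1e5)  # 100 windows
  wins$n_total <- 10L
  wins$rate <- rep(0.99, 100)
  wins$rate[37] <- 0.2
  wins$n_event <- round(wins$rate * 10)
  out <- suppressWarnings(percentile_outliers(wins, "bottom", 1))
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 36e5)
  expect_equal(out$end, 37e5)
  # all tied: everything selected and flagged
  wins$rate <- rep(0.5, 100)
  out2 <- suppressWarnings(percentile_outliers(wins, "bottom", 1))
  expect_true(attr(out2, "tied"))
  expect_equal(out2$end - out2$start, 1e7)  # merged into one region
  # overlapping selected windows merge
  iv <- data.frame(chrom = "1", start = c(0, 1e5), end = c(5e5, 6e5))
  m <- merge_intervals(iv)
  expect_equal(m, data.frame(chrom = "1", start = 0, end = 6e5))
  # top tail selects the high end
  wins$rate <- seq(0.01, 1, length.out = 100)
  top <- suppressWarnings(percentile_outliers(wins, "top", 2))
  expect_equal(nrow(top), 1)
  expect_equal(top$start, 98e5)
})

test_that("recurrent regions require the minimum number of samples", {
  shared <- data.frame(chrom = "1", start = 1e6, end = 1.5e6)
  mk <- function(extra_start) rbind(shared, data.frame(
    chrom = "1", start = extra_start, end = extra_start + 2e5))
  outliers <- list(s1 = mk(3e6), s2 = mk(5e6), s3 = mk(7e6),
                   s4 = data.frame(chrom = "1", start = 9e6, end = 9.2e6))
  rec <- recurrent_regions(outliers, min_samples = 3)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$start, 1e6)
  expect_equal(rec$n_samples, 3)
  # a region in only 2 of 4 samples is dropped
  outliers2 <- list(s1 = shared, s2 = shared,
                    s3 = data.frame(chrom = "1", start = 3e6, end = 4e6),
                    s4 = data.frame(chrom = "1", start = 5e6, end = 6e6))
  rec2 <- recurrent_regions(outliers2, min_samples = 3)
  expect_equal(nrow(rec2), 0)
})

test_that("het windows use exact 50-SNP blocks and drop the remainder", {
  cs <- make_callset(rep(0L, 100))
  hw <- het_windows(cs, 50)
  expect_equal(hw$n_het, c(0L, 0L))
  cs2 <- make_callset(rep(c(1L, 0L), 60))  # 120 calls
  hw2 <- het_windows(cs2, 50)
  expect_equal(nrow(hw2), 2)
  expect_equal(hw2$n_het, c(25L, 25L))
  # missing calls are skipped, not counted into blocks
  d <- rep(0L, 130); d[1:30] <- NA
  hw3 <- het_windows(make_callset(d), 50)
  expect_equal(nrow(hw3), 2)
})

test_that("het windows inside a planted ROH are all zero", {
  panel <- small_panel(n_sites = 4000)
  tr <- simulate_truth(panel, 1,
                       roh_plan = data.frame(sample = 1, chrom = "1",
                                             start = 2e6, end = 8e6),
                       seed = 33)
  hw <- het_windows(tr$callsets[[1]], 50)
  interior <- hw$start >= 2e6 & hw$end <= 8e6
  expect_true(sum(interior) > 5)
  expect_true(all(hw$n_het[interior] == 0))
})

test_that("region exclusion removes exactly the covered sites everywhere", {
  panel <- small_panel(n_sites = 1000)
  tr <- simulate_truth(panel, 2, seed = 34)
  regions <- data.frame(chrom = "1", start = c(1e6, 5e6), end = c(2e6, 6e6))
  n_inside <- sum((panel$sites$pos >= 1e6 & panel$sites$pos < 2e6) |
                    (panel$sites$pos >= 5e6 & panel$sites$pos < 6e6))
  filt <- exclude_regions(tr$callsets, regions)
  expect_equal(nrow(filt[[1]]$sites), 1000 - n_inside)
  expect_identical(filt[[1]]$sites$pos, filt[[2]]$sites$pos)
  # identity and annihilation limits
  expect_equal(nrow(exclude_regions(tr$callsets[[1]],
                                    regions[0, ])$sites), 1000)
  all_cover <- data.frame(chrom = "1", start = 0, end = 1e7)
  expect_equal(nrow(exclude_regions(tr$callsets[[1]], all_cover)$sites), 0)
})

test_that("a planted error hotspot lands in the bottom-1% concordance windows", {
  panel <- small_panel(n_sites = 20000, chrom_lengths = c("1" = 2e7),
                       seed = 35)
  tr <- simulate_truth(panel, 1, seed = 36)
  imp <- simulate_imputed(tr$callsets[[1]], error_model(), 1, seed = 37)
  # corrupt one 500 kb region: flip hets to hom at 10x the background
  hot <- panel$sites$pos >= 1e7 & panel$sites$pos < 1.05e7
  set.seed(38)
  flip <- hot & tr$callsets[[1]]$dosage == 1L & runif(20000) < 0.5
  imp$dosage[flip] <- 0L
  imp$gp[flip, ] <- rep(c(0.99, 0.005, 0.005), each = sum(flip))
  tab_sites <- !is.na(tr$callsets[[1]]$dosage) &
    tr$callsets[[1]]$dosage %in% c(1L, 2L) & !is.na(imp$dosage)
  correct <- tab_sites & imp$dosage == tr$callsets[[1]]$dosage
  wins <- make_windows(c("1" = 2e7), 5e5, 1e5)
  wr <- window_rates(panel$sites, tab_sites, correct, wins)
  out <- percentile_outliers(wr, "bottom", 1)
  covers_hot <- any(out$chrom == "1" & out$start < 1.05e7 & out$end > 1e7)
  expect_true(covers_hot)
})
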