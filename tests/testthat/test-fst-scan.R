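test_that("wc_fst agrees with the hand-coded variance-component oracle", {
  set.seed(100)
  for (i in 1:1000) {
    l <- random_locus()
    got <- wc_fst(l$n1, l$ac1, l$het1, l$n2, l$ac2, l$het2)
    want <- wc_fst_oracle(l$n1, l$ac1, l$het1, l$n2, l$ac2, l$het2)
    if (is.na(want)) expect_true(is.na(got)) else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("wc_fst boundary behaviour: fixation gives 1, monomorphic gives NA", {
  expect_equal(wc_fst(20, 40, 0, 25, 0, 0), 1)
  expect_true(is.na(wc_fst(20, 0, 0, 25, 0, 0)))
  expect_true(is.na(wc_fst(20, 40, 0, 25, 50, 0)))   # both fixed for alt
  expect_true(is.na(wc_fst(1, 1, 1, 25, 10, 4)))     # n < 2
})

test_that("wc_fst is near zero for equal frequencies in large samples", {
  set.seed(200)
  p <- runif(200, 0.1, 0.9)
  g1 <- matrix(rbinom(200 * 100, 2, rep(p, 100)), ncol = 100)
  g2 <- matrix(rbinom(200 * 100, 2, rep(p, 100)), ncol = 100)
  th <- wc_fst(100, rowSums(g1), rowSums(g1 == 1),
               100, rowSums(g2), rowSums(g2 == 1))
  expect_lt(abs(mean(th, na.rm = TRUE)), 0.01)
  expect_true(all(abs(th) < 0.08, na.rm = TRUE))
})

test_that("assign_bins produces balanced quintiles and matches a sort-based oracle", {
  set.seed(3)
  n <- 200
  wins <- data.table::data.table(chrom = "c",
                                 start = seq(0, by = 1e5, length.out = n),
                                 end = seq(1e5, by = 1e5, length.out = n))
  lk <- data.table::data.table(chrom = "c", start = wins$start, end = wins$end,
                               cmmb = runif(n, 0, 10))
  bins <- assign_bins(wins, lk)
  tab <- table(bins)
  expect_equal(length(tab), 5L)
  expect_lte(max(tab) - min(tab), 1L)
  # sorted values fall in increasing bins
  expect_true(all(diff(bins[order(lk$cmmb)]) >= 0))
  # 10 known values: edges equal brute-force percentiles
  v10 <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  lk10 <- data.table::data.table(chrom = "c", start = seq(0, 9) * 1e5,
                                 end = seq(1, 10) * 1e5, cmmb = v10)
  w10 <- lk10[, .(chrom, start, end)]
  b10 <- assign_bins(w10, lk10)
  want <- findInterval(v10, quantile(v10, c(0.2, 0.4, 0.6, 0.8), type = 7),
                       left.open = TRUE) + 1L
  expect_equal(b10, want)
})

test_that("assign_bins handles ties and missing linkage values", {
  wins <- data.table::data.table(chrom = "c", start = seq(0, 9) * 1e5,
                                 end = seq(1, 10) * 1e5)
  lk_const <- data.table::data.table(chrom = "c", start = wins$start,
                                     end = wins$end, cmmb = 2.5)
  expect_equal(assign_bins(wins, lk_const), rep(1L, 10))
  lk_gap <- lk_const[1:5]
  b <- assign_bins(wins, lk_gap)
  expect_true(all(is.na(b[6:10])))
})

test_that("binwise outliers flag ~1% per bin and bins are independent", {
  set.seed(8)
  n <- 5000
  x <- data.table::data.table(chrom = "c", pos = seq_len(n) * 100,
                              fst = rnorm(n, 0.02, 0.01),
                              bin = sample(1:5, n, replace = TRUE))
  fl <- binwise_outliers(x)
  rate <- tapply(fl, x$bin, mean)
  expect_true(all(rate > 0.003 & rate < 0.02))
  # shifting one bin leaves other bins' flags unchanged
  x2 <- data.table::copy(x)
  x2[bin == 3, fst := fst + 0.5]
  fl2 <- binwise_outliers(x2)
  expect_identical(fl[x$bin != 3], fl2[x2$bin != 3])
  expect_warning(binwise_outliers(x[1:50]), "< 100 SNPs")
})

test_that("window enrichment P values match the term-by-term binomial oracle", {
  expect_equal(binom_tail_oracle(5, 100, 0.01), 0.003432322, tolerance = 1e-6)
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:200, 1); k <- sample(0:10, 1); p0 <- runif(1, 0.001, 0.1)
    expect_equal(pbinom(k - 1, n, p0, lower.tail = FALSE),
                 binom_tail_oracle(k, n, p0), tolerance = 1e-10)
  }
  # k = 0 always gives P = 1
  expect_equal(pbinom(-1, 50, 0.01, lower.tail = FALSE), 1)
})

test_that("enrichment P is monotone in k and in p0", {
  n <- 100
  p_k <- sapply(0:20, function(k) pbinom(k - 1, n, 0.01, lower.tail = FALSE))
  expect_true(all(diff(p_k) <= 0))
  p_p <- sapply(seq(0.001, 0.2, length.out = 30),
                function(p0) pbinom(4, n, p0, lower.tail = FALSE))
  expect_true(all(diff(p_p) >= 0))
})

test_that("window_enrichment builds the scan, filters thin windows, and merges adjacent hits", {
  set.seed(21)
  lay <- genome_layout("c", 2e6)
  n <- 1200
  snps <- data.table::data.table(
    chrom = "c", pos = sort(sample(0:(2e6 - 1), n)),
    fst = rnorm(n, 0.02, 0.01), bin = 1L)
  snps[, outlier := fst > quantile(fst, 0.99)]
  # make two adjacent windows solid outlier blocks
  snps[pos >= 5e5 & pos < 7e5, outlier := TRUE]
  scan <- window_enrichment(snps, lay)
  expect_true(all(scan$windows$n_snps >= 10))
  enr <- scan$windows[enriched == TRUE]
  expect_true(all(c(5e5, 6e5) %in% enr$win_start))
  expect_true(nrow(scan$merged) < scan$n_enriched ||
                all(diff(sort(enr$win_start)) > 1e5))
  # the planted adjacent windows merged into one continuous region
  expect_true(any(scan$merged$start <= 5e5 & scan$merged$end >= 7e5))
  expect_true(all(scan$windows$p_value >= 0 & scan$windows$p_value <= 1))
})

test_that("repeated_overlap_test: degenerate and planted-maximum cases", {
  lay <- genome_layout(c("c1", "c2"), c(1e7, 1e7))
  enr <- regions(rep(c("c1", "c2"), each = 3),
                 rep(c(1e5, 4e5, 7e5), 2), rep(c(2e5, 5e5, 8e5), 2))
  bg <- regions(rep(c("c1", "c2"), each = 2), rep(c(0, 9e5), 2),
                rep(c(1e5, 1e6), 2))
  # candidates = whole genome: all windows overlap, chi-squared 0, P = 1
  whole <- regions(c("c1", "c2"), c(0, 0), c(1e7, 1e7))
  out <- repeated_overlap_test(enr, bg, whole, lay, n_perm = 50, seed = 1)
  expect_equal(out$chisq_obs, 0)
  expect_equal(out$p_empirical, 1)
  # enriched placed inside candidates, background outside: empirical P = 0
  cand <- merge_regions(enr, 0)
  bg2 <- regions(rep("c1", 4), c(2e6, 3e6, 5e6, 8e6),
                 c(2e6, 3e6, 5e6, 8e6) + 5e4)
  out2 <- repeated_overlap_test(enr, bg2, cand, lay, n_perm = 100, seed = 2)
  expect_equal(out2$p_empirical, 0)
  expect_match(out2$p_label, "^< ")
  expect_error(repeated_overlap_test(enr, bg, regions(character(), numeric(),
                                                      numeric()), lay),
               "empty")
})

test_that("overlap_percentages reports the published arithmetic", {
  # 71 of 1037 enriched windows overlapping: 6.85%
  enr <- regions("c", seq(0, by = 2e5, length.out = 1037),
                 seq(0, by = 2e5, length.out = 1037) + 1e5)
  cand <- regions("c", enr$start[1:71] + 5e4, enr$start[1:71] + 6e4)
  got <- overlap_percentages(enr, cand)
  expect_equal(got$n_overlapping, 71L)
  expect_equal(got$pct_enriched_overlapping, 6.85)
  expect_equal(got$pct_candidates_hit, 100)
  # disjoint and nested cases
  far <- regions("c", 1e9, 1e9 + 10)
  expect_equal(overlap_percentages(enr, far)$pct_enriched_overlapping, 0)
  expect_equal(overlap_percentages(enr[1:5], merge_regions(enr[1:5], 1e9)
                                   )$pct_enriched_overlapping, 100)
})
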