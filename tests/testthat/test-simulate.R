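small_layout <- function() genome_layout(c("chr1", "chr2"), c(4e6, 3e6))

test_that("landscape generator is deterministic and population-symmetric without signal", {
  p <- landscape_params(layout = small_layout(), n_subsets = 2,
                        noise_sd = 0, divergent_segments = 0, seed = 99)
  s1 <- simulate_landscapes(p)
  s2 <- simulate_landscapes(p)
  expect_identical(s1$maps$map, s2$maps$map)
  # zero noise + zero divergence: the two populations' maps are identical
  m_p1 <- s1$maps[population == "pop1" & subset == 1, map][[1]]
  m_p2 <- s1$maps[population == "pop2" & subset == 1, map][[1]]
  expect_equal(m_p1$rate, m_p2$rate)
})

test_that("with zero estimation noise, replicate maps correlate perfectly", {
  p <- landscape_params(layout = small_layout(), n_subsets = 3,
                        noise_sd = 0, seed = 5)
  s <- simulate_landscapes(p)
  reps <- s$maps[population == "pop1", map]
  expect_equal(cor(reps[[1]]$rate, reps[[2]]$rate, method = "spearman"), 1)
  expect_equal(cor(reps[[2]]$rate, reps[[3]]$rate, method = "spearman"), 1)
})

test_that("planted hotspots stand above their local background by more than 3 SD", {
  p <- landscape_params(layout = small_layout(), hotspots = 6,
                        spot_amp_sd = 4, seed = 21)
  s <- simulate_landscapes(p)
  tr <- bin_average(s$maps$map[[1]], 2000, s$layout)
  lr <- log(tr$value)
  hb <- 10  # +/- 20 kb in 2 kb bins
  for (k in seq_len(nrow(s$truth$hotspots))) {
    h <- s$truth$hotspots[k]
    i <- which(tr$chrom == h$chrom & tr$start >= h$start & tr$start < h$end)[1]
    ch_idx <- which(tr$chrom == h$chrom)
    j <- intersect(ch_idx, setdiff((i - hb):(i + hb), (i - 1):(i + 1)))
    z <- (lr[i] - mean(lr[j])) / sd(lr[j])
    expect_gt(z, 3)
  }
})

test_that("divergent segments shift population 2 only where planted", {
  p <- landscape_params(layout = small_layout(), n_subsets = 2, noise_sd = 0,
                        divergent_segments = 1, divergent_width_bp = 200000,
                        divergent_shift = 1.5, seed = 8)
  s <- simulate_landscapes(p)
  m1 <- s$maps[population == "pop1" & subset == 1, map][[1]]
  m2 <- s$maps[population == "pop2" & subset == 1, map][[1]]
  bins <- regions(m1$chrom, m1$start, m1$end)
  inside <- overlaps_any(bins, s$truth$divergent)
  dif <- log(m2$rate) - log(m1$rate)
  expect_equal(unique(round(dif[inside], 10)), 1.5)
  expect_true(all(abs(dif[!inside]) < 1e-12))
})

test_that("genotype generator: planted windows carry elevated F_ST, background tracks F_base", {
  p <- divergence_params(layout = genome_layout(c("chr1", "chr2"), c(8e6, 8e6)),
                         planted = 4,
                         f_base = 0.02, f_high = 0.4, seed = 31)
  g <- simulate_genotypes(p)
  pts <- regions(g$snps$chrom, g$snps$pos, g$snps$pos + 1)
  inside <- overlaps_any(pts, g$truth)
  expect_gt(mean(g$snps$fst[inside], na.rm = TRUE),
            mean(g$snps$fst[!inside], na.rm = TRUE) + 0.1)
  # realized background mean F_ST within +/- 20% of F_base
  bg <- g$snps$fst[!inside]
  expect_gt(length(bg), 5000)
  expect_lt(abs(mean(bg, na.rm = TRUE) - 0.02) / 0.02, 0.20)
})

test_that("genotype generator: no planted signal means no inside/outside contrast", {
  p <- divergence_params(layout = small_layout(), planted = 0,
                         f_base = 0.05, f_high = 0.05, seed = 13)
  g <- simulate_genotypes(p)
  # plant pseudo-windows and check indistinguishability
  set.seed(1)
  fake <- regions("chr1", c(5e5, 2e6), c(6e5, 21e5))
  pts <- regions(g$snps$chrom, g$snps$pos, g$snps$pos + 1)
  inside <- overlaps_any(pts, fake)
  tt <- t.test(g$snps$fst[inside], g$snps$fst[!inside])
  expect_gt(tt$p.value, 0.01)
})

test_that("zero missing rate writes a VCF with no missing genotypes", {
  p <- divergence_params(layout = genome_layout("chr1", 5e5),
                         missing_rate = 0, seed = 2)
  g <- simulate_genotypes(p)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(g$snps$chrom, g$snps$pos, g$gt, g$layout, f)
  expect_false(any(grepl("\\./\\.", readLines(f))))
  st <- read_snp_vcf(f)
  expect_equal(st$n1, rep(p$n1, nrow(st)))
  # counts in the VCF match the generator's table
  expect_equal(st$ac1, g$snps$ac1)
  expect_equal(st$het2, g$snps$het2)
})

test_that("SV generator conserves counts and honours coldspot placement", {
  lay <- small_layout()
  sv <- simulate_svs(sv_params(counts = c(DEL = 10, INS = 10, INV = 2), seed = 4),
                     lay)
  expect_equal(nrow(sv$svs), 22L)
  expect_equal(unname(catalogue_summary(sv$svs)$counts),
               c(10L, 10L, 2L))
  cold <- regions(c("chr1", "chr2"), c(1e6, 5e5), c(1.2e6, 7e5))
  sv2 <- simulate_svs(sv_params(counts = c(DEL = 30, INS = 30, INV = 5),
                                frac_in_coldspots = 1, seed = 4), lay, cold)
  expect_true(all(overlaps_any(sv_spans(sv2$svs), cold)))
})

test_that("planted outlier SVs rank in the top F_ST percentile", {
  lay <- small_layout()
  sv <- simulate_svs(sv_params(counts = c(DEL = 300, INS = 280, INV = 8),
                               planted_outliers = 5, outlier_gap = 0.8,
                               seed = 17), lay)
  flags <- sv_fst_outliers(sv$svs, q = 0.99)
  expect_true(all(sv$truth %in% sv$svs$sv_id[flags]))
})

test_that("planted outlier SVs can be co-located with supplied regions", {
  lay <- small_layout()
  reg <- regions(c("chr1", "chr2"), c(1e6, 2e6), c(11e5, 21e5))
  sv <- simulate_svs(sv_params(counts = c(DEL = 100, INS = 100, INV = 4),
                               planted_outliers = 10, seed = 23),
                     lay, outlier_regions = reg)
  planted <- sv$svs[sv$svs$sv_id %in% sv$truth]
  expect_true(all(overlaps_any(regions(planted$chrom, planted$pos,
                                       planted$pos + 1), reg)))
})

test_that("all generators are deterministic under a fixed seed", {
  lay <- small_layout()
  g1 <- simulate_genotypes(divergence_params(layout = lay, seed = 6))
  g2 <- simulate_genotypes(divergence_params(layout = lay, seed = 6))
  expect_identical(g1$snps, g2$snps)
  s1 <- simulate_svs(sv_params(seed = 6), lay)
  s2 <- simulate_svs(sv_params(seed = 6), lay)
  expect_identical(s1$svs, s2$svs)
  f1 <- simulate_ld_features(seed = 6)
  f2 <- simulate_ld_features(seed = 6)
  expect_identical(f1, f2)
})
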