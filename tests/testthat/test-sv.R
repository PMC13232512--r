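test_that("catalogue_summary conserves counts, handles empty catalogues", {
  sv <- sv_table(sv_id = paste0("s", 1:6), chrom = "c",
                 pos = c(0, 10, 20, 30, 40, 50) * 1000,
                 type = c("DEL", "DEL", "INS", "INS", "INS", "INV"),
                 length_bp = c(100, 300, 200, 250, 2000, 5000))
  cs <- catalogue_summary(sv)
  expect_equal(cs$total, 6L)
  expect_equal(unname(cs$counts), c(2L, 3L, 1L))
  expect_equal(sum(cs$counts), cs$total)
  expect_equal(unname(cs$mean_length["DEL"]), 200)
  empty <- sv_table(character(), character(), numeric(), character(), numeric())
  expect_equal(catalogue_summary(empty)$total, 0L)
  expect_equal(unname(catalogue_summary(empty)$counts), c(0L, 0L, 0L))
})

test_that("sv_fst_outliers flags the strict top percentile; ties flag nothing", {
  x <- sv_table(sv_id = paste0("s", 1:200), chrom = "c",
                pos = seq_len(200) * 1000, type = "DEL", length_bp = 100)
  x$fst <- seq(0, 0.995, length.out = 200)
  fl <- sv_fst_outliers(x)
  expect_equal(sum(fl), 2L)           # strict > of the type-7 99th percentile
  expect_true(all(which(fl) > 195))
  x$fst <- rep(0.3, 200)
  expect_equal(sum(sv_fst_outliers(x)), 0L)
})

test_that("sv_overlap_fisher reconstructs the published odds ratio from printed proportions", {
  # 386 outlier SVs, 78.2% overlapping (302); 37,549 background, 21.8% (8,186)
  n_out <- 386; n_bg <- 37549
  k_out <- 302; k_bg <- 8186
  lay <- genome_layout("c", 1e9)
  enr <- regions("c", 0, 1e6)
  pos <- c(seq(0, length.out = k_out, by = 100),            # outlier, inside
           seq(2e6, length.out = n_out - k_out, by = 100),  # outlier, outside
           seq(5e5, length.out = k_bg, by = 10),            # background, inside
           seq(5e6, length.out = n_bg - k_bg, by = 10))
  sv <- sv_table(sv_id = paste0("s", seq_along(pos)), chrom = "c", pos = pos,
                 type = "DEL", length_bp = 50)
  # sv_table sorts by position; recover outlier status from the id
  idx <- as.integer(sub("s", "", sv$sv_id))
  outlier <- idx <= n_out
  got <- sv_overlap_fisher(sv, outlier, enr, stratify = FALSE)$overall
  expect_equal(unname(got$table["overlap", "outlier"]), k_out)
  expect_equal(round(got$odds_ratio, 2), 12.9)
  expect_lt(got$p_value, 1e-100)
})

test_that("sv_overlap_fisher: equal overlap proportions give OR 1; toy table matches the hypergeometric oracle", {
  lay <- genome_layout("c", 1e7)
  enr <- regions("c", 0, 5e5)
  pos <- c(seq(1e3, length.out = 10, by = 100),    # 10 outliers inside
           seq(1e6, length.out = 10, by = 100),    # 10 outliers outside
           seq(2e3, length.out = 20, by = 100),    # 20 background inside
           seq(2e6, length.out = 20, by = 100))
  sv <- sv_table(sv_id = paste0("s", seq_along(pos)), chrom = "c", pos = pos,
                 type = "INS", length_bp = 60)
  idx <- as.integer(sub("s", "", sv$sv_id))
  got <- sv_overlap_fisher(sv, idx <= 20, enr, stratify = FALSE)$overall
  expect_equal(got$odds_ratio, 1)
  expect_gt(got$p_value, 0.99)
  # toy 2x2 (3,1,2,4) against enumeration
  tab <- matrix(c(3, 1, 2, 4), nrow = 2)
  expect_equal(fisher.test(tab)$p.value, fisher_p_oracle(tab),
               tolerance = 1e-10)
})

test_that("Fisher exact P equals hypergeometric enumeration on all 2x2 tables with margins <= 12", {
  for (m1 in 1:12) for (k1 in 1:m1) {
    m2 <- 12 - m1 + 1
    for (x in max(0, k1 - m2):min(k1, m1)) {
      tab <- matrix(c(x, m1 - x, k1 - x, m2 - (k1 - x)), nrow = 2)
      if (any(tab < 0)) next
      expect_equal(fisher.test(tab)$p.value, fisher_p_oracle(tab),
                   tolerance = 1e-9)
    }
  }
})

test_that("sv_density_control follows the occupancy rules and flags degenerate input", {
  w <- data.table::data.table(chrom = "c", win_start = c(0, 1e5, 2e5),
                              p_value = c(0.5, 0.01, 0.9))
  # one 50 kb INS contributes 1 bp; one 50 kb INV contributes its length;
  # one DEL contributes 1 bp
  sv <- sv_table(sv_id = c("i", "v", "d"), chrom = "c",
                 pos = c(10000, 110000, 210000),
                 type = c("INS", "INV", "DEL"),
                 length_bp = c(50000, 50000, 30000))
  out <- sv_density_control(sv, w)
  expect_equal(out$density$density, c(1 / 1e5, 50000 / 1e5, 1 / 1e5))
  # no SVs: density zero everywhere, correlation undefined but flagged
  none <- sv_table(character(), character(), numeric(), character(), numeric())
  out0 <- sv_density_control(none, w)
  expect_true(all(out0$density$density == 0))
  expect_null(out0$cor)
  expect_match(out0$note, "undefined")
})

test_that("sv density is null-calibrated: no association when density is independent of P", {
  set.seed(10)
  rhos <- vapply(1:10, function(i) {
    n <- 200
    w <- data.table::data.table(chrom = "c", win_start = (seq_len(n) - 1) * 1e5,
                                p_value = runif(n))
    pos <- sort(sample(0:(n * 1e5 - 200), 300))
    sv <- sv_table(sv_id = paste0("s", 1:300), chrom = "c", pos = pos,
                   type = sample(c("DEL", "INS"), 300, TRUE), length_bp = 100)
    unname(sv_density_control(sv, w)$cor$estimate)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
  expect_true(all(abs(rhos) < 0.25))
})

test_that("build_ld_features applies the proportion-covered formula and flank rules", {
  # SV length 400 at [2000, 2400); flanking SNPs at 1000 and 2000+... -> pair
  snp <- data.table::data.table(chrom = "c", pos = c(1000, 2900, 8000),
                                maf = c(0.2, 0.4, 0.1))
  ld <- data.table::data.table(chrom = "c", posA = 1000, posB = 2900, r2 = 0.7)
  sv <- sv_table(sv_id = "s1", chrom = "c", pos = 2000, type = "DEL",
                 length_bp = 400)
  out <- build_ld_features(sv, snp, ld)
  f <- out$features
  expect_equal(nrow(f), 1L)
  expect_equal(f$snp_dist, 1900)
  expect_equal(f$prop_covered, 400 / 1900)
  expect_equal(f$inv_wdist, 1 / (1900 * 0.2 * 0.4))
  expect_equal(f$r2, 0.7)

  # the documented spec case: flanks 1000 apart, SV length 400 -> 0.4
  snp2 <- data.table::data.table(chrom = "c", pos = c(1000, 2000),
                                 maf = c(0.3, 0.3))
  ld2 <- data.table::data.table(chrom = "c", posA = 1000, posB = 2000, r2 = 0.5)
  sv2 <- sv_table(sv_id = "s1", chrom = "c", pos = 1500, type = "INS",
                  length_bp = 400)
  f2 <- build_ld_features(sv2, snp2, ld2)$features
  expect_equal(f2$prop_covered, 0.4)

  # INS longer than the flank gap: proportion > 1 allowed
  sv3 <- sv_table(sv_id = "s1", chrom = "c", pos = 1500, type = "INS",
                  length_bp = 5000)
  f3 <- build_ld_features(sv3, snp2, ld2)$features
  expect_gt(f3$prop_covered, 1)

  # no SNP within 5 kb upstream: SV dropped
  snp4 <- data.table::data.table(chrom = "c", pos = c(2e5, 2.1e5),
                                 maf = c(0.3, 0.3))
  sv4 <- sv_table(sv_id = "s1", chrom = "c", pos = 3e5, type = "DEL",
                  length_bp = 100)
  out4 <- build_ld_features(sv4, snp4, ld2)
  expect_equal(nrow(out4$features), 0L)
  expect_equal(out4$n_dropped, 1L)
})

test_that("a SNP pair flanking two SVs is kept for both and flagged", {
  snp <- data.table::data.table(chrom = "c", pos = c(1000, 4000),
                                maf = c(0.2, 0.2))
  ld <- data.table::data.table(chrom = "c", posA = 1000, posB = 4000, r2 = 0.6)
  sv <- sv_table(sv_id = c("a", "b"), chrom = "c", pos = c(1500, 2500),
                 type = "DEL", length_bp = c(200, 200))
  f <- build_ld_features(sv, snp, ld)$features
  expect_equal(nrow(f), 2L)
  expect_true(all(f$shared_pair))
})

test_that("fit_ld_model detects a planted INV shift and reduces to OLS on one chromosome", {
  f <- simulate_ld_features(n = 500, type_shift = c(DEL = 0, INS = 0, INV = 0.05),
                            seed = 42)
  m <- fit_ld_model(f)
  expect_true(m$mixed)
  est <- m$emmeans
  expect_gt(est$emmean[est$type == "INV"], est$emmean[est$type == "DEL"])
  expect_gt(est$emmean[est$type == "INV"], est$emmean[est$type == "INS"])
  pdi <- m$contrasts$p.value[m$contrasts$contrast == "DEL - INV"]
  expect_lt(pdi, 0.05)

  # single chromosome: OLS fallback matches a direct lm oracle
  f1 <- f[f$chrom == f$chrom[1], ]
  expect_warning(m1 <- fit_ld_model(f1), "single chromosome")
  d <- data.frame(r2 = f1$r2, sdist = scale(f1$snp_dist),
                  swdist = scale(f1$inv_wdist),
                  prop_covered = f1$prop_covered, type = factor(f1$type))
  o <- lm(r2 ~ swdist + sdist + prop_covered + type, data = d)
  expect_equal(unname(coef(m1$fit)), unname(coef(o)), tolerance = 1e-8)
  expect_equal(m1$ranef_var, 0)
})

test_that("fit_ld_model is calibrated: near-zero random-effect variance and null type contrasts", {
  f <- simulate_ld_features(n = 400, chrom_sd = 0, seed = 7)
  m <- fit_ld_model(f)
  expect_lt(m$ranef_var, 0.0005)
  ps <- vapply(1:12, function(i) {
    ff <- simulate_ld_features(n = 300, seed = 100 + i)
    fit_ld_model(ff)$contrasts$p.value[1]
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.35)   # Tukey-adjusted null contrasts are conservative
})

test_that("spot_enrichment: whole-genome regions give ratio 1 and P 1; planted SVs give the minimum P", {
  lay <- genome_layout(c("c1", "c2"), c(1e6, 8e5))
  sv <- sv_table(sv_id = paste0("s", 1:40), chrom = rep(c("c1", "c2"), 20),
                 pos = rep(seq(1e4, 7.6e5, length.out = 20), each = 2),
                 type = "DEL", length_bp = 100)
  whole <- regions(c("c1", "c2"), c(0, 0), c(1e6, 8e5))
  e <- spot_enrichment(sv, whole, lay, n_shuffles = 50, seed = 1)
  expect_equal(e$ratio, 1)
  expect_equal(e$p_value, 1)
  # regions covering every SV, small relative to genome: strong enrichment
  sp <- regions(sv$chrom, sv$pos, sv$pos + 200)
  e2 <- spot_enrichment(sv, sp, lay, n_shuffles = 200, seed = 2)
  expect_equal(e2$observed, 40)
  expect_lte(e2$p_value, 1 / 200)
  expect_gt(e2$ratio, 2)
  expect_error(spot_enrichment(sv, regions("c2", 0, 9e5), lay, 10),
               "longer than")
})

test_that("spot_enrichment is invariant to chromosome relabeling", {
  lay <- genome_layout(c("c1", "c2"), c(1e6, 1e6))
  sv <- sv_table(sv_id = paste0("s", 1:30), chrom = rep(c("c1", "c2"), 15),
                 pos = rep(seq(1e4, 9e5, length.out = 15), each = 2),
                 type = "INS", length_bp = 80)
  sp <- regions(c("c1", "c2"), c(2e5, 4e5), c(3e5, 5e5))
  e1 <- spot_enrichment(sv, sp, lay, n_shuffles = 300, seed = 9)
  relab <- c(c1 = "c2", c2 = "c1")
  sv2 <- data.table::copy(sv)[, chrom := relab[chrom]]
  sp2 <- data.table::copy(sp)[, chrom := relab[chrom]]
  lay2 <- genome_layout(c("c2", "c1"), c(1e6, 1e6))
  e2 <- spot_enrichment(sv2, sp2, lay2, n_shuffles = 300, seed = 9)
  expect_equal(e1$observed, e2$observed)
  expect_equal(e1$p_value, e2$p_value, tolerance = 0.05)
})
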