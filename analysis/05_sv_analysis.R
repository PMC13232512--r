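#!/usr/bin/env Rscript
# Stage 5: structural variants. Catalogue summary, per-SV F_ST outliers and
# their Fisher overlap with enriched windows (overall and by size class),
# the SV-density control, LD around SVs via the flanking-SNP feature model
# with a chromosome random intercept, and SV enrichment in recombination
# hot/coldspots with 10,000 shuffles.

suppressMessages({
  library(recdiv)
  library(data.table)
})

SEED <- 1L
data_dir <- "results/data"
out_dir <- "results/sv"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

lay <- fread(file.path(data_dir, "genome_layout.tsv"))
layout <- genome_layout(lay$chrom, lay$length)
enriched <- read_bed("results/scan/enriched_windows.bed")
scan_windows <- fread("results/scan/scan_windows.tsv")

svs <- add_fst(read_sv_vcf(file.path(data_dir, "svs.vcf")))
cs <- catalogue_summary(svs)
flags <- sv_fst_outliers(svs)
fisher <- sv_overlap_fisher(svs, flags, enriched)
dens <- sv_density_control(svs, scan_windows)

## LD features around SVs: simulated feature table with a +0.05 r2 shift
## for inversions (the generator stands in for vcftools --geno-r2 output)
feats <- simulate_ld_features(n = 500,
                              type_shift = c(DEL = 0, INS = 0, INV = 0.05),
                              seed = SEED + 30L)
ldm <- fit_ld_model(feats)
fwrite(feats, file.path(out_dir, "ld_features.tsv"), sep = "\t")

## enrichment of SVs in called spots
spots1 <- read_bed("results/landscape/spots_pop1.bed")
spots2 <- read_bed("results/landscape/spots_pop2.bed")
cold1 <- spots1[label == "coldspot"]; cold2 <- spots2[label == "coldspot"]
hot1 <- spots1[label == "hotspot"]; hot2 <- spots2[label == "hotspot"]
cats <- list(
  coldspots_shared = merge_regions(rbind(cold1[overlaps_any(cold1, cold2)],
                                         cold2[overlaps_any(cold2, cold1)])[
                                           , .(chrom, start, end)], 0),
  coldspots_specific = rbind(cold1[!overlaps_any(cold1, cold2)],
                             cold2[!overlaps_any(cold2, cold1)])[
                               , .(chrom, start, end)],
  hotspots_shared = merge_regions(rbind(hot1[overlaps_any(hot1, hot2)],
                                        hot2[overlaps_any(hot2, hot1)])[
                                          , .(chrom, start, end)], 0),
  hotspots_specific = rbind(hot1[!overlaps_any(hot1, hot2)],
                            hot2[!overlaps_any(hot2, hot1)])[
                              , .(chrom, start, end)])
enr <- lapply(seq_along(cats), function(i) {
  if (nrow(cats[[i]]) == 0L) return(NULL)
  spot_enrichment(svs, cats[[i]], layout, n_shuffles = 10000,
                  seed = SEED + 40L + i)[c("observed", "expected", "ratio",
                                           "p_value")]
})
names(enr) <- names(cats)

jsonlite::write_json(
  list(catalogue = list(total = cs$total, counts = as.list(cs$counts),
                        mean_length = as.list(cs$mean_length)),
       n_outlier_svs = sum(flags),
       fisher = lapply(fisher, function(f)
         list(odds_ratio = f$odds_ratio, p = f$p_value)),
       density_cor = if (!is.null(dens$cor))
         list(rho = unname(dens$cor$estimate), p = dens$cor$p.value) else NULL,
       ld_model = list(contrasts = ldm$contrasts, ranef_var = ldm$ranef_var),
       spot_enrichment = enr),
  file.path(out_dir, "sv_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

inv_del <- -ldm$contrasts$estimate[ldm$contrasts$contrast == "DEL - INV"]
fmt_or <- function(x) if (!is.finite(x)) "undefined (zero margin)" else
  sprintf("%.2f", x)
cat(sprintf(
  paste0("Structural variants (%d: %d DEL, %d INS, %d INV):\n",
         "  %d F_ST outlier SVs; overlap with enriched windows OR = %s",
         " (P = %.2g); small %s / large %s\n",
         "  SV density vs scan P: Spearman rho = %.3f\n",
         "  LD model: INV r2 exceeds DEL by %.3f (contrast P = %.3g)\n",
         "  SVs in shared coldspots: %s observed vs %.1f expected",
         " (ratio %.2f, P = %.4f)\n"),
  cs$total, cs$counts["DEL"], cs$counts["INS"], cs$counts["INV"],
  sum(flags), fmt_or(fisher$overall$odds_ratio), fisher$overall$p_value,
  fmt_or(fisher$small$odds_ratio), fmt_or(fisher$large$odds_ratio),
  unname(dens$cor$estimate), inv_del,
  ldm$contrasts$p.value[ldm$contrasts$contrast == "DEL - INV"],
  enr$coldspots_shared$observed, enr$coldspots_shared$expected,
  enr$coldspots_shared$ratio, enr$coldspots_shared$p_value))
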