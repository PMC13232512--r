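#!/usr/bin/env Rscript
# Stage 4: nucleotide diversity and the recombination / diversity /
# differentiation models: windowed pi per population and its between-
# population t-test, log(F_ST) ~ recombination x pi per population, and the
# LD-map-versus-pedigree-map residual analysis with category contrasts.

suppressMessages({
  library(recdiv)
  library(data.table)
})

data_dir <- "results/data"
out_dir <- "results/diversity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

lay <- fread(file.path(data_dir, "genome_layout.tsv"))
layout <- genome_layout(lay$chrom, lay$length)
linkage <- read_linkage_map(file.path(data_dir, "linkage_map.tsv"))
candidates <- read_bed(file.path(data_dir, "candidate_regions.bed"))
enriched <- read_bed("results/scan/enriched_windows.bed")

snps <- add_fst(read_snp_vcf(file.path(data_dir, "snps.vcf")))
pi1 <- windowed_pi(snps$chrom, snps$pos, snps$ac1, 2 * snps$n1, layout)
pi2 <- windowed_pi(snps$chrom, snps$pos, snps$ac2, 2 * snps$n2, layout)
pit <- pi_population_test(pi1$pi, pi2$pi)

snps[, win_start := floor(pos / 1e5) * 1e5]
wfst <- snps[!is.na(fst), .(fst = mean(fst)), by = .(chrom, win_start)]
wd <- merge(pi1[, .(chrom, win_start = start, pi1 = pi)],
            pi2[, .(chrom, win_start = start, pi2 = pi)],
            by = c("chrom", "win_start"))
wd <- merge(wd, wfst, by = c("chrom", "win_start"), all.x = TRUE)
wd <- merge(wd, linkage[, .(chrom, win_start = start, cmmb)],
            by = c("chrom", "win_start"), all.x = TRUE)
mod1 <- fst_pi_recomb_model(wd$fst, wd$cmmb, wd$pi1)
mod2 <- fst_pi_recomb_model(wd$fst, wd$cmmb, wd$pi2)

## LD-based rho per window: mean across the 12 replicate maps
map_files <- list.files(data_dir, pattern = "^recmap_.*\\.tsv$",
                        full.names = TRUE)
rho_tracks <- vapply(map_files, function(f) {
  bin_average(read_recmap(f), 1e5, layout)$value
}, numeric(nrow(tile_genome(layout, 1e5))))
grid <- tile_genome(layout, 1e5)
wd <- merge(wd, grid[, .(chrom, win_start = start,
                         rho = rowMeans(rho_tracks, na.rm = TRUE))],
            by = c("chrom", "win_start"), all.x = TRUE)
lmr <- ld_map_residuals(wd$rho, wd$cmmb)
wreg <- regions(wd$chrom, wd$win_start, wd$win_start + 1e5)
is_enr <- overlaps_any(wreg, enriched)
is_rep <- overlaps_any(wreg, candidates)
wd[, category := fifelse(is_enr & is_rep, "outlier_repeated",
                         fifelse(is_enr, "outlier", "background"))]
wd[, residual := lmr$residuals]
rt <- residual_tests(wd$residual, wd$pi1, wd$fst, wd$category)
fwrite(wd, file.path(out_dir, "window_table.tsv"), sep = "\t")

jsonlite::write_json(
  list(pi = list(pop1 = mean(pi1$pi), pop2 = mean(pi2$pi),
                 t = unname(pit$statistic), p = pit$p.value),
       model_pop1 = list(interaction = mod1$interaction, adj_r2 = mod1$adj_r2),
       model_pop2 = list(interaction = mod2$interaction, adj_r2 = mod2$adj_r2),
       residuals = list(cor_pi = unname(rt$cor_pi$estimate),
                        cor_fst = unname(rt$cor_fst$estimate),
                        means = as.list(rt$category_means))),
  file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf(
  paste0("Diversity and selection models:\n",
         "  mean pi: pop1 = %.5f, pop2 = %.5f (t = %.2f, P = %.2f)\n",
         "  log(F_ST) ~ rec x pi: interaction %.3g (pop1), %.3g (pop2);",
         " adj R2 %.3f / %.3f\n",
         "  LD-map residuals: cor with pi %.3f, with log F_ST %.3f;",
         " category means bg %.3f / outlier %.3f / repeated %.3f\n"),
  mean(pi1$pi), mean(pi2$pi), unname(pit$statistic), pit$p.value,
  mod1$interaction, mod2$interaction, mod1$adj_r2, mod2$adj_r2,
  unname(rt$cor_pi$estimate), unname(rt$cor_fst$estimate),
  rt$category_means["background"], rt$category_means["outlier"],
  rt$category_means["outlier_repeated"]))
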