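#!/usr/bin/env Rscript
# Stage 1: generate every input the analysis consumes and write it to disk
# in the standard formats (map TSVs, SNP/SV VCFs, linkage-map TSV, truth
# BEDs), so later stages exercise the same readers a real dataset would.

suppressMessages({
  library(recdiv)
  library(data.table)
})

SEED <- 1L
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

layout <- genome_layout(paste0("chr", 1:3), rep(12e6, 3))
fwrite(as.data.table(layout), file.path(data_dir, "genome_layout.tsv"),
       sep = "\t")

## replicate recombination landscapes: 2 populations x 6 subsets, with
## planted hotspots/coldspots and two divergent segments
lp <- landscape_params(layout = layout, hotspots = 15, coldspots = 15,
                       divergent_segments = 2, divergent_shift = 1.5,
                       seed = SEED)
sim <- simulate_landscapes(lp)
for (i in seq_len(nrow(sim$maps))) {
  f <- sprintf("recmap_%s_s%d.tsv", sim$maps$population[i], sim$maps$subset[i])
  write_recmap(sim$maps$map[[i]], file.path(data_dir, f))
}
write_bed(sim$truth$hotspots, file.path(data_dir, "truth_hotspots.bed"))
write_bed(sim$truth$coldspots, file.path(data_dir, "truth_coldspots.bed"))
write_bed(sim$truth$divergent, file.path(data_dir, "truth_divergent.bed"))

## pedigree-style linkage map: the shared landscape at 100 kb, in cM/Mb
base_map <- sim$maps[population == "pop1" & subset == 1, map][[1]]
lk <- bin_average(base_map, 1e5, layout)[!is.na(value)]
write_linkage_map(lk[, .(chrom, start, end, cmmb = value * 1e8)],
                  file.path(data_dir, "linkage_map.tsv"))

## two-population SNP genotypes with 8 planted high-divergence windows;
## the truth windows double as the candidate "repeated region" set
gsim <- simulate_genotypes(divergence_params(layout = layout, planted = 8,
                                             seed = SEED + 1L))
write_snp_vcf(gsim$snps$chrom, gsim$snps$pos, gsim$gt, layout,
              file.path(data_dir, "snps.vcf"))
write_bed(gsim$truth, file.path(data_dir, "candidate_regions.bed"))

## SV catalogue: one fifth placed inside the true coldspots, and the
## planted frequency-divergent SVs inside the differentiated windows
svsim <- simulate_svs(sv_params(frac_in_coldspots = 0.2,
                                planted_outliers = 12, seed = SEED + 2L),
                      layout, coldspots = sim$truth$coldspots,
                      outlier_regions = gsim$truth)
write_sv_vcf(svsim$svs, layout, file.path(data_dir, "svs.vcf"), gt = svsim$gt)

cat(sprintf(
  "Simulated inputs written to %s:\n  %d replicate maps (%d bins each), %d SNPs, %d SVs\n  planted: %d hotspots, %d coldspots, %d divergent segments, %d F_ST windows\n",
  data_dir, nrow(sim$maps), nrow(sim$maps$map[[1]]), nrow(gsim$snps),
  nrow(svsim$svs), nrow(sim$truth$hotspots), nrow(sim$truth$coldspots),
  nrow(sim$truth$divergent), nrow(gsim$truth)))
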