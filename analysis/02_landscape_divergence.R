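#!/usr/bin/env Rscript
# Stage 2: compare the two populations' recombination landscapes.
# Computes windowed replicate correlations, the PRDI summary (against
# neutral maps regenerated under a shared landscape), the delta-r outlier
# scan, and hotspot/coldspot calls with their sharing summary.

suppressMessages({
  library(recdiv)
  library(data.table)
})

SEED <- 1L
data_dir <- "results/data"
out_dir <- "results/landscape"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

lay <- fread(file.path(data_dir, "genome_layout.tsv"))
layout <- genome_layout(lay$chrom, lay$length)

map_files <- list.files(data_dir, pattern = "^recmap_.*\\.tsv$",
                        full.names = TRUE)
meta <- data.table(
  file = map_files,
  population = sub("recmap_(pop[12])_s[0-9]+\\.tsv", "\\1", basename(map_files)),
  subset = as.integer(sub(".*_s([0-9]+)\\.tsv", "\\1", basename(map_files))))
maps <- lapply(seq_len(nrow(meta)),
               function(i) read_recmap(meta$file[i], meta$population[i],
                                       meta$subset[i]))
tracks <- lapply(maps, bin_average, width = 2000, layout = layout)

## empirical divergence me and neutral ms -> PRDI
panel <- window_spearman(tracks, meta$population, window = 5e6)
me <- compute_me(panel)
neutral <- simulate_landscapes(landscape_params(layout = layout, seed = SEED + 10L))
tracks_n <- lapply(neutral$maps$map, bin_average, width = 2000, layout = layout)
panel_n <- window_spearman(tracks_n, neutral$maps$population, window = 5e6)
ms <- compute_me(panel_n)
prdi <- compute_prdi(me, ms)
profile <- prdi_profile(panel, panel_n)
fwrite(profile, file.path(out_dir, "prdi_profile.tsv"), sep = "\t")

## delta-r outliers over all replicate pairs
pairs <- utils::combn(length(tracks), 2)
dr <- rbindlist(lapply(seq_len(ncol(pairs)), function(k) {
  i <- pairs[1, k]; j <- pairs[2, k]
  d <- delta_r(tracks[[i]], tracks[[j]])
  d[, type := if (meta$population[i] == meta$population[j]) "within" else "between"]
  d
}))
dro <- delta_r_outliers(dr[type == "within"], dr[type == "between"])
fwrite(dro$windows, file.path(out_dir, "delta_r_windows.tsv"), sep = "\t")
if (nrow(dro$outliers)) write_bed(dro$outliers,
                                  file.path(out_dir, "delta_r_outliers.bed"))

## hotspots and coldspots per population (median track over replicates)
med_track <- function(pop) {
  tt <- tracks[meta$population == pop]
  m <- copy(tt[[1]])
  m[, value := apply(vapply(tt, function(t) t$value, numeric(nrow(m))),
                     1, median, na.rm = TRUE)]
  setattr(m, "width", 2000)
  m
}
spots <- lapply(c("pop1", "pop2"), function(p) call_spots(med_track(p)))
names(spots) <- c("pop1", "pop2")
for (p in names(spots)) {
  write_bed(spots[[p]][, .(chrom, start, end, label = kind, score = peak_z)],
            file.path(out_dir, paste0("spots_", p, ".bed")))
}
hot <- lapply(spots, function(s) s[kind == "hotspot"])
cold <- lapply(spots, function(s) s[kind == "coldspot"])
sh <- sharing_summary(hot$pop1, hot$pop2)
sc <- sharing_summary(cold$pop1, cold$pop2)

truth_div <- read_bed(file.path(data_dir, "truth_divergent.bed"))
hit <- if (nrow(dro$outliers)) sum(overlaps_any(truth_div, dro$outliers)) else 0

cat(sprintf(
  paste0("Landscape divergence:\n",
         "  me = %.4f (within medians %.3f / %.3f, between %.3f), ms = %.4f",
         " -> PRDI = %.4f\n",
         "  delta-r outlier windows: %d (planted divergent segments hit:",
         " %d of %d)\n",
         "  hotspots %d/%d (shared %d, %d%% of pop1); coldspots %d/%d",
         " (shared %d, %d%% of pop1)\n"),
  me$me, me$within_medians[1], me$within_medians[2], me$between_median,
  ms$me, prdi$prdi, nrow(dro$outliers), hit, nrow(truth_div),
  sh$n_a, sh$n_b, sh$shared, sh$pct_of_a,
  sc$n_a, sc$n_b, sc$shared, sc$pct_of_a))
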