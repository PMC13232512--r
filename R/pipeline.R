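# End-to-end orchestration on synthetic data: generate inputs, run every
# analysis stage, and emit a machine-readable report of the statistics the
# pipeline computes.

#' Pipeline run configuration
#'
#' All tunables with their study defaults: 2 kb recombination bins, 5 Mb
#' correlation windows, 100 kb scan windows, >= 10 SNPs per window, per-bin
#' 99th-percentile outlier SNPs, 0.05 binomial enrichment cut, +/- 20 kb
#' spot background with z = 3, 1 kb spot merge gap, 5 kb hotspot length
#' cap, 500 window permutations, 10,000 SV shuffles, 5 kb SV flanks.
#' Synthetic-generation parameters nest under `landscape`, `divergence` and
#' `sv`.
#'
#' @param seed global seed; stage seeds are derived deterministically.
#' @param landscape,divergence,sv generator parameter lists (see
#'   [landscape_params()], [divergence_params()], [sv_params()]); the global
#'   layout and derived seeds are injected.
#' @param ... override any scalar tunable (see defaults in the function).
#' @return `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       landscape = list(hotspots = 15, coldspots = 15,
                                        divergent_segments = 2,
                                        divergent_shift = 1.5),
                       divergence = list(planted = 8),
                       sv = list(frac_in_coldspots = 0.2,
                                 planted_outliers = 12),
                       ...) {
  cfg <- list(
    seed = as.integer(seed),
    bin_width = 2000,
    corr_window = 5e6,
    scan_window = 1e5,
    min_snps = 10,
    outlier_quantile = 0.99,
    enrich_alpha = 0.05,
    spot_half_window = 20000,
    spot_z = 3,
    spot_merge_gap = 1000,
    hotspot_max_len = 5000,
    n_perm_windows = 500,
    n_shuffles_sv = 10000,
    sv_flank = 5000,
    delta_r_eps = 1e-12,
    inv_ld_shift = 0.05,
    landscape = landscape,
    divergence = divergence,
    sv = sv
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

# deterministic stage seeds below 2^31
stage_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2000000011L

#' Run the full analysis pipeline on synthetic data
#'
#' Generates every input with the synthetic-data module, then runs the
#' landscape-divergence, differentiation-scan, diversity/selection and SV
#' stages, and returns (and optionally writes) a report of every statistic
#' computed: PRDI and its components, delta-r outliers, spot sharing
#' counts, enriched-window counts and overlap percentages,
#' chi-squared/Fisher/permutation outputs, and model coefficients.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory; when given, the JSON report and
#'   BED/TSV tracks are written there.
#' @return the report (nested list), invisibly also written to
#'   `file.path(outdir, "report.json")` when `outdir` is set.
#' @export
run_all <- function(config = run_config(), outdir = NULL) {
  cfg <- config
  report <- list(config = cfg[setdiff(names(cfg), c("landscape", "divergence", "sv"))])

  ## stage 1: synthetic inputs ------------------------------------------------
  lp <- do.call(landscape_params, c(cfg$landscape,
                                    list(seed = stage_seed(cfg$seed, 1L))))
  sim <- simulate_landscapes(lp)
  layout <- sim$layout
  neutral_lp <- lp
  neutral_lp$divergent_segments <- 0
  neutral_lp$divergent_shift <- 0
  neutral_lp$seed <- stage_seed(cfg$seed, 2L)
  sim_neutral <- simulate_landscapes(neutral_lp)

  dp <- do.call(divergence_params, c(cfg$divergence,
                                     list(layout = layout,
                                          seed = stage_seed(cfg$seed, 3L))))
  gsim <- simulate_genotypes(dp)

  ## linkage map: the shared landscape averaged at scan resolution,
  ## converted to cM/Mb (rate/bp/gen * 1e8)
  base_map <- sim$maps[population == "pop1" & subset == 1, map][[1]]
  lk_track <- bin_average(base_map, cfg$scan_window, layout)
  linkage <- lk_track[, .(chrom, start, end, cmmb = value * 1e8)]
  linkage <- linkage[!is.na(cmmb)]

  ## stage 2: landscape divergence -------------------------------------------
  tracks <- lapply(sim$maps$map, bin_average, width = cfg$bin_width,
                   layout = layout)
  pops <- sim$maps$population
  panel <- window_spearman(tracks, pops, window = cfg$corr_window)
  me <- compute_me(panel)
  tracks_n <- lapply(sim_neutral$maps$map, bin_average,
                     width = cfg$bin_width, layout = layout)
  panel_n <- window_spearman(tracks_n, sim_neutral$maps$population,
                             window = cfg$corr_window)
  ms <- compute_me(panel_n)
  prdi <- compute_prdi(me, ms)
  profile <- prdi_profile(panel, panel_n)

  pairs <- utils::combn(length(tracks), 2)
  dr <- rbindlist(lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- delta_r(tracks[[i]], tracks[[j]], window = cfg$scan_window,
                 eps = cfg$delta_r_eps)
    d[, type := if (pops[i] == pops[j]) "within" else "between"]
    d
  }))
  dro <- delta_r_outliers(dr[type == "within"], dr[type == "between"],
                          z = 3, window = cfg$scan_window)

  med_track <- function(pop) {
    tt <- tracks[pops == pop]
    m <- copy(tt[[1]])
    vals <- vapply(tt, function(t) t$value, numeric(nrow(m)))
    m[, value := apply(vals, 1, median, na.rm = TRUE)]
    setattr(m, "width", cfg$bin_width)
    m
  }
  spots1 <- call_spots(med_track("pop1"), cfg$spot_half_window, cfg$spot_z,
                       cfg$spot_merge_gap, cfg$hotspot_max_len)
  spots2 <- call_spots(med_track("pop2"), cfg$spot_half_window, cfg$spot_z,
                       cfg$spot_merge_gap, cfg$hotspot_max_len)
  hot1 <- spots1[kind == "hotspot"]; hot2 <- spots2[kind == "hotspot"]
  cold1 <- spots1[kind == "coldspot"]; cold2 <- spots2[kind == "coldspot"]
  share_hot <- sharing_summary(hot1, hot2)
  share_cold <- sharing_summary(cold1, cold2)

  report$landscape <- list(
    me = me$me, ms = ms$me, prdi = prdi$prdi,
    within_medians = as.list(me$within_medians),
    between_median = me$between_median,
    prdi_profile_range = range(profile$prdi),
    n_delta_r_outliers = nrow(dro$outliers),
    hotspots = list(pop1 = nrow(hot1), pop2 = nrow(hot2),
                    shared = share_hot$shared,
                    pct_of_pop1 = share_hot$pct_of_a,
                    pct_of_pop2 = share_hot$pct_of_b,
                    pct_of_total = share_hot$pct_of_total),
    coldspots = list(pop1 = nrow(cold1), pop2 = nrow(cold2),
                     shared = share_cold$shared,
                     pct_of_pop1 = share_cold$pct_of_a,
                     pct_of_pop2 = share_cold$pct_of_b,
                     pct_of_total = share_cold$pct_of_total)
  )

  ## stage 3: differentiation scan -------------------------------------------
  snps <- copy(gsim$snps)
  wins <- tile_genome(layout, cfg$scan_window)
  wins[, bin := assign_bins(wins, linkage)]
  snps[, win_start := floor(pos / cfg$scan_window) * cfg$scan_window]
  snps[wins, bin := i.bin, on = c(chrom = "chrom", win_start = "start")]
  snps[, outlier := suppressWarnings(
    binwise_outliers(snps, q = cfg$outlier_quantile))]
  scan <- window_enrichment(snps, layout, window = cfg$scan_window,
                            min_snps = cfg$min_snps, alpha = cfg$enrich_alpha)
  candidates <- gsim$truth
  non_enriched <- scan$windows[enriched == FALSE]
  background <- if (nrow(non_enriched)) {
    regions(non_enriched$chrom, non_enriched$win_start,
            pmin(non_enriched$win_start + cfg$scan_window,
                 chrom_length(layout, non_enriched$chrom)))
  } else regions(character(), numeric(), numeric())
  ovt <- if (cfg$n_perm_windows > 0 && nrow(candidates) > 0 &&
             nrow(scan$enriched) > 0) {
    repeated_overlap_test(scan$enriched, background, candidates, layout,
                          n_perm = cfg$n_perm_windows,
                          seed = stage_seed(cfg$seed, 4L))
  } else NULL
  ovp <- if (nrow(candidates) > 0) {
    overlap_percentages(scan$enriched, candidates)
  } else NULL

  report$scan <- list(
    n_snps = nrow(snps), p0 = scan$p0,
    n_windows = nrow(scan$windows),
    n_enriched = scan$n_enriched, n_merged = scan$n_merged,
    bin_uniformity_p = if (!is.null(scan$bin_uniformity))
      scan$bin_uniformity$p.value else NULL,
    p_vs_snpcount_r = if (!is.null(scan$p_vs_snpcount))
      unname(scan$p_vs_snpcount$estimate) else NULL,
    overlap_test = if (!is.null(ovt)) list(
      chisq_obs = ovt$chisq_obs, p_empirical = ovt$p_empirical,
      p_label = ovt$p_label, perm_mean = ovt$perm_mean,
      perm_sd = ovt$perm_sd) else "skipped",
    overlap_percentages = ovp
  )

  ## stage 4: diversity & selection ------------------------------------------
  st <- snps
  pi1 <- windowed_pi(st$chrom, st$pos, st$ac1, 2 * st$n1, layout,
                     window = cfg$scan_window)
  pi2 <- windowed_pi(st$chrom, st$pos, st$ac2, 2 * st$n2, layout,
                     window = cfg$scan_window)
  pit <- pi_population_test(pi1$pi, pi2$pi)
  wfst <- st[!is.na(fst), .(fst = mean(fst)),
             by = .(chrom, win_start)]
  wd <- merge(pi1[, .(chrom, win_start = start, pi1 = pi)],
              pi2[, .(chrom, win_start = start, pi2 = pi)],
              by = c("chrom", "win_start"))
  wd <- merge(wd, wfst, by = c("chrom", "win_start"), all.x = TRUE)
  wd <- merge(wd, linkage[, .(chrom, win_start = start, cmmb)],
              by = c("chrom", "win_start"), all.x = TRUE)
  mod1 <- fst_pi_recomb_model(wd$fst, wd$cmmb, wd$pi1)
  mod2 <- fst_pi_recomb_model(wd$fst, wd$cmmb, wd$pi2)

  rho_track <- bin_average(base_map, cfg$scan_window, layout)
  ## rho with replicate noise: mean over pop maps at scan resolution
  rho_vals <- rowMeans(vapply(sim$maps$map,
                              function(m) bin_average(m, cfg$scan_window,
                                                      layout)$value,
                              numeric(nrow(rho_track))), na.rm = TRUE)
  wd2 <- rho_track[, .(chrom, win_start = start, rho = rho_vals)]
  wd <- merge(wd, wd2, by = c("chrom", "win_start"), all.x = TRUE)
  lmr <- ld_map_residuals(wd$rho, wd$cmmb)
  wreg <- regions(wd$chrom, wd$win_start, wd$win_start + cfg$scan_window)
  is_enr <- overlaps_any(wreg, scan$enriched)
  is_rep <- if (nrow(candidates)) overlaps_any(wreg, candidates) else
    rep(FALSE, nrow(wd))
  category <- fifelse(is_enr & is_rep, "outlier_repeated",
                      fifelse(is_enr, "outlier", "background"))
  rt <- residual_tests(lmr$residuals, wd$pi1, wd$fst, category)

  report$diversity <- list(
    pi_mean = list(pop1 = mean(pi1$pi), pop2 = mean(pi2$pi)),
    pi_t = unname(pit$statistic), pi_p = pit$p.value,
    model_pop1 = list(interaction = mod1$interaction, adj_r2 = mod1$adj_r2,
                      n_used = mod1$n_used),
    model_pop2 = list(interaction = mod2$interaction, adj_r2 = mod2$adj_r2,
                      n_used = mod2$n_used),
    residual_cor_pi = unname(rt$cor_pi$estimate),
    residual_cor_fst = unname(rt$cor_fst$estimate),
    residual_means = as.list(rt$category_means)
  )

  ## stage 5: structural variants --------------------------------------------
  svp <- do.call(sv_params, c(cfg$sv, list(seed = stage_seed(cfg$seed, 5L))))
  svsim <- simulate_svs(svp, layout, coldspots = sim$truth$coldspots,
                        outlier_regions = gsim$truth)
  svs <- svsim$svs
  cat_sum <- catalogue_summary(svs)
  svo <- sv_fst_outliers(svs, q = cfg$outlier_quantile)
  fisher <- sv_overlap_fisher(svs, svo, scan$enriched)
  dens <- sv_density_control(svs, scan$windows, window = cfg$scan_window)
  feats <- simulate_ld_features(
    n = 500, type_shift = c(DEL = 0, INS = 0, INV = cfg$inv_ld_shift),
    seed = stage_seed(cfg$seed, 6L))
  ldm <- fit_ld_model(feats)
  spot_cats <- list(
    coldspots_shared = merge_regions(
      rbind(cold1[overlaps_any(cold1, cold2)],
            cold2[overlaps_any(cold2, cold1)], fill = TRUE)[, .(chrom, start, end)],
      max_gap = 0),
    coldspots_specific = rbind(cold1[!overlaps_any(cold1, cold2)],
                               cold2[!overlaps_any(cold2, cold1)],
                               fill = TRUE)[, .(chrom, start, end)],
    hotspots_shared = merge_regions(
      rbind(hot1[overlaps_any(hot1, hot2)],
            hot2[overlaps_any(hot2, hot1)], fill = TRUE)[, .(chrom, start, end)],
      max_gap = 0),
    hotspots_specific = rbind(hot1[!overlaps_any(hot1, hot2)],
                              hot2[!overlaps_any(hot2, hot1)],
                              fill = TRUE)[, .(chrom, start, end)]
  )
  enr_res <- if (cfg$n_shuffles_sv > 0) {
    lapply(seq_along(spot_cats), function(i) {
      rg <- spot_cats[[i]]
      if (nrow(rg) == 0L) return("skipped")
      e <- spot_enrichment(svs, rg, layout, n_shuffles = cfg$n_shuffles_sv,
                           seed = stage_seed(cfg$seed, 7L + i))
      e[c("observed", "expected", "ratio", "p_value")]
    })
  } else as.list(rep("skipped", length(spot_cats)))
  names(enr_res) <- names(spot_cats)

  report$sv <- list(
    total = cat_sum$total, counts = as.list(cat_sum$counts),
    mean_length = as.list(cat_sum$mean_length),
    n_outliers = sum(svo),
    fisher_overall = list(odds_ratio = fisher$overall$odds_ratio,
                          p_value = fisher$overall$p_value),
    fisher_small = list(odds_ratio = fisher$small$odds_ratio,
                        p_value = fisher$small$p_value),
    fisher_large = list(odds_ratio = fisher$large$odds_ratio,
                        p_value = fisher$large$p_value),
    density_cor = if (!is.null(dens$cor)) unname(dens$cor$estimate) else NULL,
    ld_model = list(
      inv_minus_del = -ldm$contrasts$estimate[
        ldm$contrasts$contrast == "DEL - INV"],
      inv_minus_ins = ldm$contrasts$estimate[
        ldm$contrasts$contrast == "INS - INV"] * -1,
      contrast_p = ldm$contrasts$p.value[ldm$contrasts$contrast == "DEL - INV"],
      ranef_var = ldm$ranef_var),
    spot_enrichment = enr_res
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    write_bed(scan$enriched, file.path(outdir, "enriched_windows.bed"))
    if (nrow(spots1)) write_bed(spots1[, .(chrom, start, end, label = kind,
                                           score = peak_z)],
                                file.path(outdir, "spots_pop1.bed"))
    if (nrow(spots2)) write_bed(spots2[, .(chrom, start, end, label = kind,
                                           score = peak_z)],
                                file.path(outdir, "spots_pop2.bed"))
    fwrite(profile, file.path(outdir, "prdi_profile.tsv"), sep = "\t")
    fwrite(scan$windows, file.path(outdir, "scan_windows.tsv"), sep = "\t")
  }
  report
}
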