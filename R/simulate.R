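# Synthetic-data generators. These emulate, at desk scale, the statistical
# structure of the study inputs: replicate LD-based recombination maps for
# two connected populations (autocorrelated log-normal landscapes with
# replicate estimation noise, planted hotspots/coldspots and divergent
# segments), two-population SNP genotypes under a Balding-Nichols F-model
# with planted high-divergence windows, an SV catalogue, and LD features
# around SVs.

#' Parameters for synthetic recombination landscapes
#'
#' Defaults emulate the study conditions at reduced scale: two populations
#' with several replicate map subsets each; log-normal rates centred at
#' ~1e-8 per bp per generation with SD ~1 on the natural-log scale;
#' landscape autocorrelation over tens of kb; replicate estimation noise.
#' Hotspot/coldspot amplitudes are expressed in SD units of the local (+/-
#' 20 kb) background of the final noisy track.
#'
#' @param layout a [genome_layout()]; default three 12 Mb chromosomes.
#' @param n_subsets replicate map subsets per population.
#' @param bin_width resolution of the generated landscape (bp).
#' @param log_mean,log_sd mean and SD of the natural-log recombination rate.
#' @param autocorr_bp Gaussian smoothing length-scale of the log-rate field.
#' @param noise_sd per-replicate estimation-noise SD (log scale).
#' @param hotspots,coldspots number of planted spots per population.
#' @param spot_width_bp planted spot width.
#' @param spot_amp_sd spot amplitude in local-background SD units
#'   (hotspots +, coldspots -).
#' @param divergent_segments number of segments where population 2's
#'   landscape is shifted.
#' @param divergent_width_bp width of each divergent segment.
#' @param divergent_shift log-rate shift applied to population 2 inside
#'   divergent segments.
#' @param seed RNG seed.
#' @return a `landscape_params` list.
#' @export
landscape_params <- function(layout = genome_layout(paste0("chr", 1:3), rep(12e6, 3)),
                             n_subsets = 6,
                             bin_width = 2000,
                             log_mean = log(1e-8),
                             log_sd = 1,
                             autocorr_bp = 50000,
                             noise_sd = 0.3,
                             hotspots = 0,
                             coldspots = 0,
                             spot_width_bp = 3000,
                             spot_amp_sd = 4,
                             divergent_segments = 0,
                             divergent_width_bp = 200000,
                             divergent_shift = 0,
                             seed = 1L) {
  stopifnot(noise_sd >= 0, n_subsets >= 2, bin_width > 0)
  structure(as.list(environment()), class = "landscape_params")
}

# Gaussian moving-average smoothing of white noise, unit marginal variance
.smooth_field <- function(n, scale_bins) {
  z <- rnorm(n + 6 * ceiling(scale_bins))
  k <- dnorm(seq(-3 * scale_bins, 3 * scale_bins), sd = scale_bins)
  k <- k / sqrt(sum(k^2))   # preserves unit variance
  f <- stats::filter(z, k, sides = 2)
  f <- f[!is.na(f)]
  f[seq_len(n)]
}

# spot starts snap to the landscape generation grid (`snap` = bin width):
# the landscape is a bin-resolution field, so planted features are too
.place_spots <- function(layout, n, width, min_edge = 40000, snap = 1) {
  if (n == 0) return(regions(character(), numeric(), numeric()))
  ch <- sample(layout$chrom, n, replace = TRUE,
               prob = layout$length / sum(layout$length))
  clen <- chrom_length(layout, ch)
  s <- floor(runif(n, min_edge, clen - width - min_edge))
  s <- floor(s / snap) * snap
  merge_regions(regions(ch, s, s + width), max_gap = 0)
}

# local (+/- half_window) SD of a value vector on a bin grid, per chromosome
.local_sd <- function(dt, half_bins) {
  dt[, {
    v <- value
    n <- .N
    sapply(seq_len(n), function(i) {
      j <- max(1, i - half_bins):min(n, i + half_bins)
      sd(v[j])
    })
  }, by = chrom]$V1
}

#' Simulate replicate recombination landscapes for two populations
#'
#' Both populations share one autocorrelated Gaussian log-rate field;
#' population 2's field is shifted by `divergent_shift` inside planted
#' divergent segments; planted hotspots/coldspots shift the local log-rate
#' by `spot_amp_sd` local-background SDs (spots are shared between
#' populations; the divergence machinery is the divergent segments). Each
#' replicate subset then receives independent Gaussian estimation noise.
#'
#' @param params a [landscape_params()].
#' @return list with `maps` (a `data.table` keyed by `population`, `subset`
#'   holding one `recmap` per row in `map`), `truth` (region sets:
#'   `hotspots`, `coldspots`, `divergent`), `layout`, and `params`.
#' @export
simulate_landscapes <- function(params = landscape_params()) {
  p <- params
  set.seed(p$seed)
  layout <- p$layout
  bins <- tile_genome(layout, p$bin_width)
  bins <- bins[end - start == p$bin_width]  # complete bins only
  scale_bins <- p$autocorr_bp / p$bin_width
  base <- bins[, .(chrom, start, end)]
  base[, value := p$log_mean + p$log_sd * .smooth_field(.N, scale_bins), by = chrom]

  half_bins <- ceiling(20000 / p$bin_width)
  hot <- .place_spots(layout, p$hotspots, p$spot_width_bp, snap = p$bin_width)
  cold <- .place_spots(layout, p$coldspots, p$spot_width_bp, snap = p$bin_width)
  div <- .place_spots(layout, p$divergent_segments, p$divergent_width_bp,
                      snap = p$bin_width)
  if (nrow(div) && any(div$end > chrom_length(layout, div$chrom))) {
    stop("divergent segment outside chromosome")
  }

  # amplitude calibrated to the local background SD of the *noisy* track
  loc_sd <- sqrt(.local_sd(base, half_bins)^2 + p$noise_sd^2)
  spot_shift <- rep(0, nrow(base))
  if (nrow(hot)) {
    idx <- which(overlaps_any(regions(base$chrom, base$start, base$end), hot))
    spot_shift[idx] <- spot_shift[idx] + p$spot_amp_sd * loc_sd[idx]
  }
  if (nrow(cold)) {
    idx <- which(overlaps_any(regions(base$chrom, base$start, base$end), cold))
    spot_shift[idx] <- spot_shift[idx] - p$spot_amp_sd * loc_sd[idx]
  }

  div_shift <- rep(0, nrow(base))
  if (nrow(div)) {
    idx <- which(overlaps_any(regions(base$chrom, base$start, base$end), div))
    div_shift[idx] <- p$divergent_shift
  }

  fields <- list(pop1 = base$value + spot_shift,
                 pop2 = base$value + spot_shift + div_shift)

  maps <- CJ(population = c("pop1", "pop2"), subset = seq_len(p$n_subsets))
  maps[, map := {
    lapply(seq_len(.N), function(i) {
      lr <- fields[[population[i]]] +
        if (p$noise_sd > 0) rnorm(nrow(base), 0, p$noise_sd) else 0
      as_recmap(data.table(chrom = base$chrom, start = base$start,
                           end = base$end, rate = exp(lr)),
                population = population[i], subset = subset[i])
    })
  }]
  list(maps = maps,
       truth = list(hotspots = hot, coldspots = cold, divergent = div),
       layout = layout, params = p)
}

#' Parameters for synthetic two-population SNP genotypes
#'
#' Balding-Nichols F-model: each SNP draws an ancestral frequency, then each
#' population draws its frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F = f_base` (or `f_high`
#' inside planted windows); diploid genotypes are binomial. SNPs whose
#' pooled-sample minor allele frequency is below `maf_min` are dropped, as
#' in the study's SNP filter.
#'
#' @param layout a [genome_layout()].
#' @param snp_density expected SNPs per bp (default 1/2000 => ~50 SNPs per
#'   100 kb window).
#' @param f_base baseline differentiation level, in (0, 1).
#' @param f_high differentiation inside planted windows.
#' @param planted number of planted 100 kb high-divergence windows.
#' @param planted_width_bp width of planted windows.
#' @param n1,n2 diploid sample sizes.
#' @param missing_rate per-genotype missingness probability.
#' @param maf_min pooled minor-allele-frequency filter.
#' @param seed RNG seed.
#' @return `divergence_params` list.
#' @export
divergence_params <- function(layout = genome_layout(paste0("chr", 1:3), rep(12e6, 3)),
                              snp_density = 1 / 2000,
                              f_base = 0.02,
                              f_high = 0.4,
                              planted = 0,
                              planted_width_bp = 100000,
                              n1 = 40, n2 = 40,
                              missing_rate = 0.02,
                              maf_min = 0.05,
                              seed = 1L) {
  stopifnot(f_base > 0, f_base < 1, f_high >= f_base, f_high < 1,
            n1 >= 2, n2 >= 2, missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "divergence_params")
}

.bn_freq <- function(p, f) {
  if (f <= 0) return(p)
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate two-population SNP genotypes
#'
#' @param params a [divergence_params()].
#' @return list with `snps` (a `snp_table` with `fst` added), `gt` (list of
#'   two genotype dosage matrices), `truth` (region set of planted windows),
#'   `layout`, `params`.
#' @export
simulate_genotypes <- function(params = divergence_params()) {
  p <- params
  set.seed(p$seed)
  layout <- p$layout
  n_snp <- rbinom(nrow(layout), size = as.integer(layout$length),
                  prob = p$snp_density)
  pos <- unlist(lapply(seq_len(nrow(layout)), function(i) {
    sort(floor(runif(n_snp[i], 0, layout$length[i])))
  }))
  chrom <- rep(layout$chrom, n_snp)

  planted <- .place_spots(layout, p$planted, p$planted_width_bp, min_edge = 0)
  in_planted <- if (nrow(planted)) {
    overlaps_any(regions(chrom, pos, pos + 1), planted)
  } else rep(FALSE, length(pos))

  panc <- runif(length(pos), 0.05, 0.95)
  fvec <- ifelse(in_planted, p$f_high, p$f_base)
  p1 <- rbeta(length(pos), panc * (1 - fvec) / fvec, (1 - panc) * (1 - fvec) / fvec)
  p2 <- rbeta(length(pos), panc * (1 - fvec) / fvec, (1 - panc) * (1 - fvec) / fvec)

  g1 <- matrix(rbinom(length(pos) * p$n1, 2, rep(p1, p$n1)), ncol = p$n1)
  g2 <- matrix(rbinom(length(pos) * p$n2, 2, rep(p2, p$n2)), ncol = p$n2)
  if (p$missing_rate > 0) {
    g1[matrix(runif(length(g1)) < p$missing_rate, nrow(g1))] <- NA_integer_
    g2[matrix(runif(length(g2)) < p$missing_rate, nrow(g2))] <- NA_integer_
  }

  n1g <- rowSums(!is.na(g1)); n2g <- rowSums(!is.na(g2))
  ac1 <- rowSums(g1, na.rm = TRUE); ac2 <- rowSums(g2, na.rm = TRUE)
  af <- (ac1 + ac2) / (2 * (n1g + n2g))
  maf <- pmin(af, 1 - af)
  keep <- maf >= p$maf_min & n1g >= 2 & n2g >= 2
  snps <- snp_table(chrom = chrom[keep], pos = pos[keep],
                    n1 = n1g[keep], ac1 = ac1[keep],
                    het1 = rowSums(g1 == 1L, na.rm = TRUE)[keep],
                    n2 = n2g[keep], ac2 = ac2[keep],
                    het2 = rowSums(g2 == 1L, na.rm = TRUE)[keep])
  snps <- add_fst(snps)
  # snp_table sorts by (chrom, pos); reorder matrices to match
  ord <- order(chrom[keep], pos[keep])
  list(snps = snps,
       gt = list(pop1 = g1[keep, , drop = FALSE][ord, , drop = FALSE],
                 pop2 = g2[keep, , drop = FALSE][ord, , drop = FALSE]),
       truth = planted, layout = layout, params = p)
}

#' Parameters for a synthetic SV catalogue
#'
#' Default type counts and per-type log-normal length distributions follow
#' the catalogue composition of the study system (deletions ~200 bp,
#' insertions ~300 bp, inversions ~3 kb; deletions and insertions dominate,
#' inversions rare) at a scale set by `counts`.
#'
#' @param counts named integer vector of SV counts (`DEL`, `INS`, `INV`).
#' @param len_meanlog,len_sdlog named per-type log-normal length parameters.
#' @param len_min minimum SV length (bp).
#' @param frac_in_coldspots fraction of SVs placed inside supplied coldspots.
#' @param n1,n2 diploid sample sizes for SV genotypes.
#' @param planted_outliers number of SVs given a large between-population
#'   frequency gap.
#' @param outlier_gap frequency gap for planted outlier SVs.
#' @param seed RNG seed.
#' @return `sv_params` list.
#' @export
sv_params <- function(counts = c(DEL = 500, INS = 450, INV = 10),
                      len_meanlog = c(DEL = log(216), INS = log(292), INV = log(3117)),
                      len_sdlog = c(DEL = 0.8, INS = 0.8, INV = 1.0),
                      len_min = 50,
                      frac_in_coldspots = 0,
                      n1 = 40, n2 = 40,
                      planted_outliers = 0,
                      outlier_gap = 0.8,
                      seed = 1L) {
  stopifnot(all(counts >= 0), frac_in_coldspots >= 0, frac_in_coldspots <= 1)
  structure(as.list(environment()), class = "sv_params")
}

#' Simulate a structural-variant catalogue with genotypes
#'
#' SVs are placed uniformly along the genome, except a fraction
#' `frac_in_coldspots` placed uniformly inside the supplied coldspot
#' regions. Population allele frequencies are drawn from a mild F-model;
#' planted outlier SVs get frequencies separated by `outlier_gap`.
#'
#' @param params an [sv_params()].
#' @param layout a [genome_layout()].
#' @param coldspots optional region set for preferential placement.
#' @param outlier_regions optional region set; when given, planted outlier
#'   SVs are repositioned uniformly inside these regions (emulating the
#'   co-location of strongly differentiated SVs with differentiated
#'   genomic regions).
#' @return list with `svs` (an `sv_table` with `fst`), `gt` (genotype
#'   matrices), `truth` (character vector of planted outlier `sv_id`s),
#'   `layout`, `params`.
#' @export
simulate_svs <- function(params = sv_params(), layout, coldspots = NULL,
                         outlier_regions = NULL) {
  p <- params
  set.seed(p$seed)
  n <- sum(p$counts)
  type <- rep(names(p$counts), p$counts)
  len <- pmax(p$len_min, round(rlnorm(n, p$len_meanlog[type], p$len_sdlog[type])))

  in_cold <- if (!is.null(coldspots) && nrow(coldspots) > 0 && p$frac_in_coldspots > 0) {
    runif(n) < p$frac_in_coldspots
  } else rep(FALSE, n)

  chrom <- character(n); pos <- numeric(n)
  n_unif <- sum(!in_cold)
  if (n_unif > 0) {
    ch <- sample(layout$chrom, n_unif, replace = TRUE,
                 prob = layout$length / sum(layout$length))
    chrom[!in_cold] <- ch
    pos[!in_cold] <- floor(runif(n_unif, 0, pmax(1, chrom_length(layout, ch) - len[!in_cold])))
  }
  if (any(in_cold)) {
    k <- sum(in_cold)
    ci <- sample(nrow(coldspots), k, replace = TRUE,
                 prob = coldspots$end - coldspots$start)
    chrom[in_cold] <- coldspots$chrom[ci]
    # anchor inside the coldspot so the SV span overlaps it
    pos[in_cold] <- floor(runif(k, coldspots$start[ci],
                                pmax(coldspots$start[ci] + 1, coldspots$end[ci] - 1)))
  }

  af_anc <- rbeta(n, 1.2, 3)                 # skewed toward low frequencies
  af_anc <- pmin(pmax(af_anc, 0.06), 0.94)
  f1 <- .bn_freq(af_anc, 0.02)
  f2 <- .bn_freq(af_anc, 0.02)
  planted_id <- character(0)
  if (p$planted_outliers > 0) {
    pi_idx <- sample(n, min(p$planted_outliers, n))
    f1[pi_idx] <- 0.05 + (1 - p$outlier_gap - 0.1) * runif(length(pi_idx))
    f2[pi_idx] <- pmin(0.95, f1[pi_idx] + p$outlier_gap)
    planted_id <- paste0("sv", pi_idx)
    if (!is.null(outlier_regions) && nrow(outlier_regions) > 0) {
      ri <- sample(nrow(outlier_regions), length(pi_idx), replace = TRUE,
                   prob = outlier_regions$end - outlier_regions$start)
      chrom[pi_idx] <- outlier_regions$chrom[ri]
      pos[pi_idx] <- floor(runif(length(pi_idx), outlier_regions$start[ri],
                                 pmax(outlier_regions$start[ri] + 1,
                                      outlier_regions$end[ri] - 1)))
    }
  }
  f1 <- pmin(pmax(f1, 0.01), 0.99); f2 <- pmin(pmax(f2, 0.01), 0.99)
  g1 <- matrix(rbinom(n * p$n1, 2, rep(f1, p$n1)), ncol = p$n1)
  g2 <- matrix(rbinom(n * p$n2, 2, rep(f2, p$n2)), ncol = p$n2)

  svs <- sv_table(sv_id = paste0("sv", seq_len(n)), chrom = chrom, pos = pos,
                  type = type, length_bp = len,
                  n1 = rep(p$n1, n), ac1 = rowSums(g1), het1 = rowSums(g1 == 1L),
                  n2 = rep(p$n2, n), ac2 = rowSums(g2), het2 = rowSums(g2 == 1L))
  svs <- add_fst(svs)
  ord <- match(svs$sv_id, paste0("sv", seq_len(n)))
  list(svs = svs,
       gt = list(pop1 = g1[ord, , drop = FALSE], pop2 = g2[ord, , drop = FALSE]),
       truth = planted_id, layout = layout, params = p)
}

#' Simulate flanking-SNP LD features around SVs
#'
#' Generates the feature table [fit_ld_model()] consumes, under a known
#' truth: `r2 = intercept + b_dist * scaled distance + b_prop * proportion
#' covered + type shift + chromosome random intercept + noise`, truncated to
#' `[0, 1]`.
#'
#' @param n number of features.
#' @param n_chrom number of chromosomes to spread features over.
#' @param type_shift named numeric: additive r2 shift per SV type
#'   (default all 0).
#' @param b_dist,b_prop fixed-effect slopes on the standardized covariates.
#' @param chrom_sd SD of the chromosome random intercept.
#' @param noise_sd residual SD.
#' @param intercept baseline r2.
#' @param seed RNG seed.
#' @return `data.table` of LD features with a `population` column.
#' @export
simulate_ld_features <- function(n = 500, n_chrom = 5,
                                 type_shift = c(DEL = 0, INS = 0, INV = 0),
                                 b_dist = 0.01, b_prop = 0.05,
                                 chrom_sd = 0.01, noise_sd = 0.05,
                                 intercept = 0.05, seed = 1L) {
  set.seed(seed)
  type <- sample(c("DEL", "INS", "INV"), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  u <- setNames(rnorm(n_chrom, 0, chrom_sd), paste0("chr", seq_len(n_chrom)))
  dist <- runif(n, 200, 10000)
  prop <- runif(n, 0.05, 1)
  invw <- 1 / (dist * runif(n, 0.05, 0.5) * runif(n, 0.05, 0.5))
  r2 <- intercept + b_dist * as.numeric(scale(dist)) + b_prop * prop +
    type_shift[type] + u[chrom] + rnorm(n, 0, noise_sd)
  data.table(sv_id = paste0("sv", seq_len(n)), chrom = chrom, type = type,
             r2 = pmin(pmax(r2, 0), 1),
             snp_dist = dist, prop_covered = prop, inv_wdist = invw,
             population = "pop1")
}
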