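# Windowed nucleotide diversity, the F_ST ~ recombination x pi models, and
# the LD-map-versus-pedigree-map residual analysis.

#' Windowed nucleotide diversity (missing-data-aware)
#'
#' Per-site unbiased pairwise diversity summed over variant sites and
#' divided by the window length, treating unobserved sites as monomorphic
#' (the pixy-style contract): for a site with `c_ref` reference and `c_alt`
#' alternate alleles among `n = c_ref + c_alt` genotyped alleles, the site
#' term is `c_ref * c_alt / choose(n, 2)`. Missing genotypes at a variant
#' site reduce `n` for that site. Windows with no genotyped site get pi = 0
#' (monomorphic) unless the window has no SNP records and
#' `require_sites = TRUE`.
#'
#' @param chrom,pos variant coordinates (0-based).
#' @param ac alternate allele counts per site.
#' @param an total genotyped allele numbers per site (`2 * n diploids`).
#' @param layout a [genome_layout()].
#' @param window window width in bp (default 100 kb).
#' @return `data.table(chrom, start, end, pi, n_sites)` over the full
#'   genome tiling.
#' @export
windowed_pi <- function(chrom, pos, ac, an, layout, window = 1e5) {
  stopifnot(all(ac <= an))
  site <- data.table(chrom = as.character(chrom), pos = as.numeric(pos),
                     ac = as.numeric(ac), an = as.numeric(an))
  site <- site[an >= 2]
  site[, term := ac * (an - ac) / (an * (an - 1) / 2)]
  site[, win_start := floor(pos / window) * window]
  agg <- site[, .(num = sum(term), n_sites = .N), by = .(chrom, win_start)]
  bins <- tile_genome(layout, window)
  out <- merge(bins, agg, by.x = c("chrom", "start"),
               by.y = c("chrom", "win_start"), all.x = TRUE)
  out[is.na(num), `:=`(num = 0, n_sites = 0L)]
  out[, pi := num / (end - start)]
  out[, num := NULL]
  setorder(out, chrom, start)
  out[]
}

#' Test the between-population difference in windowed diversity
#'
#' Welch two-sample t-test on the per-window pi values of the two
#' populations.
#'
#' @param pi_a,pi_b numeric vectors of window pi (matched windows).
#' @return `htest` from [t.test()].
#' @export
pi_population_test <- function(pi_a, pi_b) {
  ok_a <- pi_a[!is.na(pi_a)]; ok_b <- pi_b[!is.na(pi_b)]
  if (length(ok_a) < 2 || length(ok_b) < 2) stop("need >= 2 windows per population")
  t.test(pi_a, pi_b)
}

#' Model windowed F_ST on recombination rate and diversity
#'
#' Ordinary least squares of `log(F_ST) ~ rec + pi + rec:pi` per population,
#' after dropping windows with non-positive F_ST (count reported).
#'
#' @param fst windowed F_ST values.
#' @param rec windowed recombination rates (cM/Mb from the pedigree map).
#' @param pi windowed nucleotide diversity for the focal population.
#' @return list with `fit` (the `lm`), `coefficients` (matrix),
#'   `interaction` (estimate of the `rec:pi` term), `adj_r2`,
#'   `n_used`, `n_dropped_nonpositive`, `rank_deficient` flag.
#' @export
fst_pi_recomb_model <- function(fst, rec, pi) {
  d <- data.table(fst = fst, rec = rec, pi = pi)
  d <- d[complete.cases(d)]
  n_drop <- sum(d$fst <= 0)
  d <- d[fst > 0]
  if (nrow(d) < 5) stop("too few windows with positive F_ST")
  fit <- lm(log(fst) ~ rec * pi, data = d)
  rank_def <- fit$rank < 4L || any(is.na(coef(fit)))
  if (rank_def) warning("model design is rank deficient (collinear rec and pi)")
  sm <- summary(fit)
  list(fit = fit, coefficients = sm$coefficients,
       interaction = unname(coef(fit)["rec:pi"]),
       adj_r2 = sm$adj.r.squared,
       n_used = nrow(d), n_dropped_nonpositive = n_drop,
       rank_deficient = rank_def)
}

#' Residuals of LD-based recombination on the pedigree map
#'
#' Fits `log(rho) ~ cmmb` by OLS across windows and extracts residuals:
#' windows with negative residuals have more LD (lower effective
#' recombination) than their meiotic rate predicts. Zero rates are floored
#' as in the spot caller before the log.
#'
#' @param rho per-window mean LD-based recombination rate.
#' @param cmmb per-window pedigree-map rate (cM/Mb).
#' @return list with `fit`, `residuals` (NA where input was NA), `n_used`,
#'   and `degenerate` flag (TRUE when the fit is an exact relationship and
#'   residuals are all ~0).
#' @export
ld_map_residuals <- function(rho, cmmb) {
  ok <- !is.na(rho) & !is.na(cmmb)
  lr <- rep(NA_real_, length(rho))
  lr[ok] <- .floor_log(rho[ok])
  fit <- lm(lr ~ cmmb, subset = ok)
  res <- rep(NA_real_, length(rho))
  res[ok] <- resid(fit)
  degenerate <- sd(res[ok]) < 1e-10
  if (degenerate) warning("residuals are ~0: rho is an exact function of cmmb")
  list(fit = fit, residuals = res, n_used = sum(ok), degenerate = degenerate)
}

#' Correlations and category contrasts of LD-map residuals
#'
#' Pearson correlations of the residuals with diversity and with
#' (log-transformed) F_ST, and Welch t-tests comparing residual means
#' between window categories (background, outlier windows overlapping
#' candidate repeated regions, outlier windows not overlapping them).
#'
#' @param residuals per-window residuals from [ld_map_residuals()].
#' @param pi per-window diversity (either population).
#' @param fst per-window F_ST.
#' @param category factor/character per window:
#'   `background`, `outlier`, `outlier_repeated`.
#' @param log_fst use log(F_ST) (positive values only) for the F_ST
#'   correlation (default TRUE); the raw-F_ST correlation is also returned.
#' @return list with `cor_pi`, `cor_fst` (on the chosen scale),
#'   `cor_fst_raw`, `category_means`, and Welch t-tests
#'   `t_repeated_vs_background`, `t_outlier_vs_background`,
#'   `t_repeated_vs_outlier` (NULL when a category has < 2 windows).
#' @export
residual_tests <- function(residuals, pi, fst, category, log_fst = TRUE) {
  stopifnot(length(residuals) == length(category))
  cor_pi <- cor.test(residuals, pi, method = "pearson")
  lf <- fst
  lf[!is.na(lf) & lf <= 0] <- NA
  cor_fst_log <- cor.test(residuals, log(lf), method = "pearson")
  cor_fst_raw <- cor.test(residuals, fst, method = "pearson")
  grp <- function(g) residuals[category == g & !is.na(residuals)]
  tt <- function(a, b) {
    if (length(a) >= 2 && length(b) >= 2) t.test(a, b) else NULL
  }
  bg <- grp("background"); ol <- grp("outlier"); rp <- grp("outlier_repeated")
  list(cor_pi = cor_pi,
       cor_fst = if (log_fst) cor_fst_log else cor_fst_raw,
       cor_fst_raw = cor_fst_raw,
       category_means = c(background = mean(bg), outlier = mean(ol),
                          outlier_repeated = mean(rp)),
       t_repeated_vs_background = tt(rp, bg),
       t_outlier_vs_background = tt(ol, bg),
       t_repeated_vs_outlier = tt(rp, ol))
}
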