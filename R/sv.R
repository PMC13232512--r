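# Structural-variant analyses: catalogue summaries, per-SV F_ST outliers,
# overlap with enriched windows (Fisher), SV density control, flanking-SNP
# LD features and the chromosome-random-intercept LD model, and SV
# enrichment in recombination hot/coldspots.

#' Summarize an SV catalogue
#'
#' @param svs an `sv_table`.
#' @return list with `total`, and per-type `counts`, `mean_length`,
#'   `min_length`, `max_length`.
#' @export
catalogue_summary <- function(svs) {
  x <- as.data.table(svs)
  types <- c("DEL", "INS", "INV")
  per <- if (nrow(x)) {
    x[, .(n = .N, mean_length = mean(length_bp),
          min_length = min(length_bp), max_length = max(length_bp)),
      by = type]
  } else {
    data.table(type = character(), n = integer(), mean_length = numeric(),
               min_length = numeric(), max_length = numeric())
  }
  cnt <- setNames(rep(0L, 3), types)
  cnt[per$type] <- per$n
  list(total = nrow(x), counts = cnt,
       mean_length = setNames(per$mean_length, per$type),
       min_length = setNames(per$min_length, per$type),
       max_length = setNames(per$max_length, per$type))
}

#' Flag per-SV F_ST outliers
#'
#' Outliers strictly exceed the `q` quantile of the F_ST distribution over
#' all SVs (one genome-wide threshold, as for the study's SV scan).
#'
#' @param svs `sv_table` with an `fst` column.
#' @param q quantile (default 0.99).
#' @return logical flags along `svs` (NA fst => FALSE).
#' @export
sv_fst_outliers <- function(svs, q = 0.99) {
  fst <- as.data.table(svs)$fst
  thr <- quantile(fst, q, na.rm = TRUE, type = 7)
  out <- !is.na(fst) & fst > thr
  out
}

#' Fisher test of outlier-SV overlap with enriched windows
#'
#' 2x2 contingency of (outlier / background SV) x (overlaps >= 1 enriched
#' window / does not), tested two-sided with Fisher's exact test; run
#' overall and optionally stratified into large (>= 1 kb) and small (< 1 kb)
#' SVs. Overlap uses the SV reference span ([sv_spans()]).
#'
#' @param svs `sv_table`.
#' @param outlier logical flags (from [sv_fst_outliers()]).
#' @param enriched_windows region set of enriched windows.
#' @param stratify also test per size class (default TRUE)?
#' @return list with `overall` and (optionally) `small`, `large`; each holds
#'   the `table`, `odds_ratio` (sample OR), `odds_ratio_mle` (conditional
#'   MLE from `fisher.test`), `p_value`, and a `note` when a zero margin
#'   makes the OR undefined.
#' @export
sv_overlap_fisher <- function(svs, outlier, enriched_windows, stratify = TRUE) {
  x <- as.data.table(svs)
  hits <- overlaps_any(sv_spans(x), enriched_windows)
  one <- function(sel) {
    o <- outlier[sel]; h <- hits[sel]
    tab <- matrix(c(sum(o & h), sum(o & !h), sum(!o & h), sum(!o & !h)),
                  nrow = 2,
                  dimnames = list(c("overlap", "no_overlap"),
                                  c("outlier", "background")))
    ft <- fisher.test(tab, alternative = "two.sided")
    zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    s_or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
    list(table = tab,
         odds_ratio = s_or,
         odds_ratio_mle = unname(ft$estimate),
         p_value = ft$p.value,
         note = if (zero_margin || !is.finite(s_or))
           "zero margin: odds ratio undefined (Haldane correction not applied)"
         else NULL)
  }
  out <- list(overall = one(rep(TRUE, nrow(x))))
  if (stratify) {
    out$small <- one(x$size_class == "small")
    out$large <- one(x$size_class == "large")
  }
  out
}

#' SV density per window and its association with enrichment significance
#'
#' Density is the proportion of window bases occupied by SVs, with
#' deletions counted as 1 bp (the study's rule for avoiding double-counting
#' of large deletions), insertions as their 1 bp anchor, and inversions as
#' their full length. The association with the scan's significance is the
#' Spearman correlation of density with -log10(P).
#'
#' @param svs `sv_table`.
#' @param scan_windows the `windows` table from [window_enrichment()]
#'   (needs `chrom`, `win_start`, `p_value`).
#' @param window window width in bp (default 100 kb).
#' @return list with `density` table and `cor` (`cor.test` result, or NULL
#'   with `note` when density is constant).
#' @export
sv_density_control <- function(svs, scan_windows, window = 1e5) {
  x <- as.data.table(svs)
  occ_len <- fifelse(x$type == "INV", x$length_bp, 1)
  occ <- regions(x$chrom, x$pos, x$pos + occ_len)
  w <- as.data.table(scan_windows)[, .(chrom, win_start, p_value)]
  setorder(w, chrom, win_start)   # keep row order aligned with region keys
  wreg <- regions(w$chrom, w$win_start, w$win_start + window)
  wreg[, win := .I]
  pr <- .olap_pairs(wreg, occ)
  if (nrow(pr)) {
    pr[, cov_len := pmin(wreg$end[xid], occ$end[yid]) -
         pmax(wreg$start[xid], occ$start[yid])]
    dens <- pr[, .(bp = sum(cov_len)), by = xid]
  } else dens <- data.table(xid = integer(), bp = numeric())
  w[, density := 0]
  w[dens$xid, density := dens$bp / window]
  ct <- if (sd(w$density) > 0 && nrow(w) >= 3) {
    suppressWarnings(cor.test(w$density, -log10(pmax(w$p_value, 1e-300)),
                              method = "spearman"))
  } else NULL
  list(density = w[],
       cor = ct,
       note = if (is.null(ct)) "density constant or too few windows: correlation undefined" else NULL)
}

#' Build flanking-SNP LD features around SVs
#'
#' For each SV, finds the nearest SNP strictly left of the SV span start and
#' the nearest strictly right of the span end, each within `flank` bp of its
#' breakend, looks up the pair's r-squared among the supplied LD records,
#' and computes the explanatory variables of the LD model: the flanking
#' distance (`posSNP2 - posSNP1`), the proportion of that interval covered
#' by the SV (`length_SV / (posSNP2 - posSNP1)`; may exceed 1 for
#' insertions, whose length is not on the reference), and the inverse
#' frequency-weighted distance `1 / (dist * MAF_SNP1 * MAF_SNP2)`. SVs
#' lacking either flank or the pair's r2 record are dropped (count
#' reported). A SNP pair flanking two SVs is kept for both and flagged.
#'
#' @param svs `sv_table`.
#' @param snp_pos `data.table(chrom, pos, maf)` of SNP positions (0-based)
#'   with minor allele frequencies.
#' @param ld `data.table(chrom, posA, posB, r2)` of pairwise LD records
#'   (0-based; see [read_ld_table()]).
#' @param flank maximum breakend-to-SNP distance (default 5 kb).
#' @return list with `features` (`data.table` incl. `r2`, `snp_dist`,
#'   `prop_covered`, `inv_wdist`, `type`, `chrom`, `shared_pair` flag) and
#'   `n_dropped`.
#' @export
build_ld_features <- function(svs, snp_pos, ld, flank = 5000) {
  x <- as.data.table(svs)
  sp <- as.data.table(snp_pos)
  setorder(sp, chrom, pos)
  spans <- sv_spans(x)
  spans <- spans[match(x$sv_id, spans$label)]
  feats <- rbindlist(lapply(seq_len(nrow(x)), function(i) {
    ch <- x$chrom[i]
    s <- spans$start[i]; e <- spans$end[i]
    cand <- sp[chrom == ch]
    left <- cand[pos < s & pos >= s - flank]
    right <- cand[pos >= e & pos <= e + flank]
    if (nrow(left) == 0L || nrow(right) == 0L) return(NULL)
    p1 <- left[which.max(pos)]
    p2 <- right[which.min(pos)]
    data.table(sv_id = x$sv_id[i], chrom = ch, type = x$type[i],
               length_bp = x$length_bp[i],
               pos1 = p1$pos, pos2 = p2$pos, maf1 = p1$maf, maf2 = p2$maf)
  }))
  if (is.null(feats) || nrow(feats) == 0L) {
    return(list(features = data.table(), n_dropped = nrow(x)))
  }
  ldk <- as.data.table(ld)
  feats <- merge(feats, ldk, by.x = c("chrom", "pos1", "pos2"),
                 by.y = c("chrom", "posA", "posB"), all.x = TRUE)
  n_no_ld <- sum(is.na(feats$r2))
  feats <- feats[!is.na(r2)]
  feats[, snp_dist := pos2 - pos1]
  feats[, prop_covered := length_bp / snp_dist]
  feats[, inv_wdist := 1 / (snp_dist * maf1 * maf2)]
  feats[, shared_pair := .N > 1L, by = .(chrom, pos1, pos2)]
  list(features = feats[],
       n_dropped = nrow(x) - nrow(feats))
}

#' Linear mixed model of LD around SVs
#'
#' `r2 ~ scaled(inverse frequency-weighted distance) + scaled(flanking
#' interval) + proportion covered + SV type + (1 | chromosome)`, fitted by
#' REML with lme4. Marginal means per SV type and their pairwise contrasts
#' come from emmeans. With a single chromosome the model falls back to
#' fixed-intercept OLS with a warning.
#'
#' @param features feature table from [build_ld_features()] or
#'   [simulate_ld_features()] (needs `r2`, `snp_dist`, `prop_covered`,
#'   `inv_wdist`, `type`, `chrom`).
#' @return list with `fit`, `fixed` (fixed-effect table), `ranef_var`
#'   (chromosome random-intercept variance; 0 for the OLS fallback),
#'   `emmeans` (marginal means per type), `contrasts` (pairwise contrast
#'   table), `mixed` (logical).
#' @export
fit_ld_model <- function(features) {
  d <- as.data.table(features)
  stopifnot(nrow(d) >= 10)
  d[, `:=`(sdist = as.numeric(scale(snp_dist)),
           swdist = as.numeric(scale(inv_wdist)),
           type = factor(type))]
  mixed <- length(unique(d$chrom)) >= 2
  if (mixed) {
    fit <- lme4::lmer(r2 ~ swdist + sdist + prop_covered + type + (1 | chrom),
                      data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_var <- vc$vcov[vc$grp == "chrom"]
    fixed <- coef(summary(fit))
  } else {
    warning("single chromosome: falling back to fixed-intercept OLS")
    fit <- lm(r2 ~ swdist + sdist + prop_covered + type, data = d)
    ranef_var <- 0
    fixed <- coef(summary(fit))
  }
  em <- emmeans::emmeans(fit, "type")
  ctr <- as.data.frame(emmeans::contrast(em, method = "pairwise"))
  list(fit = fit, fixed = fixed, ranef_var = ranef_var,
       emmeans = as.data.frame(em), contrasts = ctr, mixed = mixed)
}

#' SV enrichment in recombination hot/coldspots
#'
#' Counts SVs (reference spans) overlapping the region category, then
#' shuffles the regions `n_shuffles` times uniformly within their own
#' chromosomes (lengths preserved) and recounts. Enrichment ratio =
#' observed / mean(shuffled); one-sided empirical
#' P = (# shuffles with count >= observed) / n_shuffles.
#'
#' @param svs `sv_table`.
#' @param spot_regions region set (e.g. shared coldspots).
#' @param layout a [genome_layout()].
#' @param n_shuffles number of shuffles (default 10000).
#' @param seed optional RNG seed.
#' @return list with `observed`, `expected` (shuffle mean), `ratio`,
#'   `p_value`, `n_shuffles`.
#' @export
spot_enrichment <- function(svs, spot_regions, layout, n_shuffles = 10000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spans <- sv_spans(svs)
  obs <- sum(overlaps_any(spans, spot_regions))
  cnt <- vapply(seq_len(n_shuffles), function(i) {
    sum(overlaps_any(spans, shuffle_regions(spot_regions, layout)))
  }, numeric(1))
  list(observed = obs, expected = mean(cnt),
       ratio = if (mean(cnt) > 0) obs / mean(cnt) else NA_real_,
       p_value = sum(cnt >= obs) / n_shuffles,
       n_shuffles = n_shuffles)
}
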