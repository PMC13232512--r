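# Recombination-aware F_ST outlier scan: quintile bins from the pedigree
# map, per-bin 99th-percentile outlier SNPs, binomial window enrichment, and
# the candidate-region overlap tests (chi-squared + chromosome-preserving
# permutation null).

#' Assign recombination quintile bins
#'
#' Bins genomic windows into five classes by the 0-20th, 20-40th, 40-60th,
#' 60-80th and 80-100th percentiles of the genome-wide pedigree-map
#' recombination distribution. Quintile edges use the linear-interpolation
#' empirical quantile. Degenerate distributions (tied edges) collapse the
#' affected bins; windows are then assigned to the lowest applicable bin.
#'
#' @param windows `data.table(chrom, start, end)` of scan windows.
#' @param linkage linkage map `data.table(chrom, start, end, cmmb)`.
#' @return integer vector of bins 1..5 along `windows` (`NA` where the
#'   linkage map has no value for the window).
#' @export
assign_bins <- function(windows, linkage) {
  val <- value_at_bins(windows, linkage, "cmmb")
  edges <- quantile(val, probs = seq(0, 1, 0.2), na.rm = TRUE, type = 7)
  br <- unique(as.numeric(edges))
  if (length(br) == 1L) {       # fully degenerate: a single tied bin
    return(ifelse(is.na(val), NA_integer_, 1L))
  }
  bin <- as.integer(cut(val, breaks = br, include.lowest = TRUE))
  # map back onto the 1..5 scale when edges were tied
  if (length(br) < 6L) {
    lab <- which(!duplicated(as.numeric(edges)))[-1] - 1L
    bin <- lab[bin]
  }
  bin
}

#' Flag per-bin 99th-percentile F_ST outlier SNPs
#'
#' Within each recombination bin, flags SNPs whose F_ST strictly exceeds the
#' bin's `q` quantile (linear-interpolation empirical quantile).
#'
#' @param snps `snp_table` with `fst` and `bin` columns.
#' @param q quantile (default 0.99).
#' @param min_bin_snps warn when a bin has fewer SNPs than this (default
#'   100); the threshold is still computed.
#' @return logical outlier flags along `snps` (`NA` fst or bin => `FALSE`).
#' @export
binwise_outliers <- function(snps, q = 0.99, min_bin_snps = 100) {
  x <- as.data.table(snps)
  stopifnot(all(c("fst", "bin") %in% names(x)))
  small <- x[!is.na(bin) & !is.na(fst), .N, by = bin][N < min_bin_snps]
  if (nrow(small)) {
    warning("bin(s) with < ", min_bin_snps, " SNPs: ",
            paste(small$bin, collapse = ", "))
  }
  flag <- rep(FALSE, nrow(x))
  ok <- !is.na(x$bin) & !is.na(x$fst)
  thr <- x[ok, .(thr = quantile(fst, q, type = 7)), by = bin]
  xx <- merge(x[ok, .(i = which(ok), fst, bin)], thr, by = "bin")
  flag[xx$i] <- xx$fst > xx$thr
  flag
}

#' Binomial window-enrichment scan
#'
#' Aggregates outlier-flagged SNPs into non-overlapping windows and computes,
#' per window, the binomial upper-tail probability of observing at least the
#' observed number of outlier SNPs given the window's SNP count and the
#' genome-wide outlier proportion (the study's "non-exact P-value";
#' dependence among SNPs precludes a formal P). Windows with fewer than
#' `min_snps` SNPs are excluded before `p0` is computed. Windows with
#' P < `alpha` are enriched; adjacent enriched windows (gap 0 on the tiling
#' grid) are merged into continuous regions. Also computes the chi-squared
#' uniformity test of enriched windows across the five recombination bins
#' and the Pearson correlation of P with SNP count (controls).
#'
#' @param snps `snp_table` with `fst`, `bin` and `outlier` columns.
#' @param layout a [genome_layout()].
#' @param window window width in bp (default 100 kb).
#' @param min_snps minimum SNPs per window (default 10).
#' @param alpha enrichment cut on the non-exact P (default 0.05).
#' @return list with `windows` (per-window scan table), `enriched` (region
#'   set of enriched windows), `merged` (adjacent enriched windows merged),
#'   `p0`, `n_enriched`, `n_merged`, `bin_uniformity`
#'   (`chisq.test` result or `NULL`), and `p_vs_snpcount`
#'   (`cor.test` result or `NULL`).
#' @export
window_enrichment <- function(snps, layout, window = 1e5, min_snps = 10,
                              alpha = 0.05) {
  x <- as.data.table(snps)
  stopifnot(all(c("outlier", "bin") %in% names(x)))
  x <- x[!is.na(fst) & !is.na(bin)]
  x[, win_start := floor(pos / window) * window]
  w <- x[, .(n_snps = .N, n_out = sum(outlier), bin = bin[1]),
         by = .(chrom, win_start)]
  w <- w[n_snps >= min_snps]
  p0 <- w[, sum(n_out) / sum(n_snps)]
  w[, p_value := pbinom(n_out - 1, n_snps, p0, lower.tail = FALSE)]
  w[, enriched := p_value < alpha]
  setorder(w, chrom, win_start)
  enr <- w[enriched == TRUE]
  enriched_regions <- if (nrow(enr)) {
    regions(enr$chrom, enr$win_start,
            pmin(enr$win_start + window, chrom_length(layout, enr$chrom)))
  } else regions(character(), numeric(), numeric())
  merged <- merge_regions(enriched_regions, max_gap = 0)
  bin_unif <- if (nrow(enr) >= 5 && length(unique(w$bin)) > 1) {
    tab <- table(factor(enr$bin, levels = sort(unique(w$bin))))
    suppressWarnings(chisq.test(tab))
  } else NULL
  pcor <- if (nrow(w) >= 3) cor.test(w$p_value, w$n_snps, method = "pearson")
          else NULL
  list(windows = w[], enriched = enriched_regions, merged = merged,
       p0 = p0, n_enriched = nrow(enr), n_merged = nrow(merged),
       bin_uniformity = bin_unif, p_vs_snpcount = pcor)
}

# Pearson chi-squared statistic (no continuity correction) of a 2x2 table
.chisq2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(e == 0)) return(0)
  sum((m - e)^2 / e)
}

#' Candidate-region overlap test with a chromosome-preserving permutation null
#'
#' Tests whether enriched windows overlap a candidate region set (e.g. the
#' known repeated targets of marine-freshwater adaptation) more often than
#' background windows: a Pearson chi-squared statistic on the 2x2 table of
#' (enriched / background) x (overlapping / not), plus an empirical P from
#' `n_perm` permutations in which the enriched windows are independently
#' repositioned uniformly within their own chromosomes (size preserved,
#' windows may not exceed chromosome ends). Empirical
#' P = (# permuted chi-squared >= observed) / n_perm, reported as
#' `< 1/n_perm` when zero.
#'
#' @param enriched region set of enriched windows.
#' @param background region set of non-enriched windows.
#' @param candidates candidate region set (must be non-empty).
#' @param layout a [genome_layout()].
#' @param n_perm number of permutations (default 500).
#' @param seed optional RNG seed.
#' @return list with the 2x2 `table`, `chisq_obs`, `perm_stats`,
#'   `p_empirical` (numeric r/n), `p_label` (string, `"< 1/n"` form when 0),
#'   `perm_mean`, `perm_sd`.
#' @export
repeated_overlap_test <- function(enriched, background, candidates, layout,
                                  n_perm = 500, seed = NULL) {
  if (nrow(candidates) == 0L) stop("candidate region set is empty")
  if (!is.null(seed)) set.seed(seed)
  ov_e <- sum(overlaps_any(enriched, candidates))
  ov_b <- sum(overlaps_any(background, candidates))
  obs <- .chisq2x2(ov_e, nrow(enriched) - ov_e, ov_b, nrow(background) - ov_b)
  perm <- vapply(seq_len(n_perm), function(i) {
    pe <- shuffle_regions(enriched, layout)
    pv <- sum(overlaps_any(pe, candidates))
    .chisq2x2(pv, nrow(pe) - pv, ov_b, nrow(background) - ov_b)
  }, numeric(1))
  r <- sum(perm >= obs)
  list(table = matrix(c(ov_e, nrow(enriched) - ov_e,
                        ov_b, nrow(background) - ov_b), nrow = 2,
                      dimnames = list(c("overlap", "no_overlap"),
                                      c("enriched", "background"))),
       chisq_obs = obs, perm_stats = perm,
       p_empirical = r / n_perm,
       p_label = if (r == 0) paste0("< ", format(1 / n_perm)) else
         format(r / n_perm),
       perm_mean = mean(perm), perm_sd = sd(perm))
}

#' Overlap percentages between enriched windows and candidate regions
#'
#' @param enriched region set of enriched windows.
#' @param candidates candidate region set.
#' @return list: `n_enriched`, `n_overlapping` (enriched windows touching
#'   >= 1 candidate), `pct_enriched_overlapping` (2 dp),
#'   `n_candidates`, `n_candidates_hit`, `pct_candidates_hit` (2 dp).
#' @export
overlap_percentages <- function(enriched, candidates) {
  ne <- nrow(enriched); nc <- nrow(candidates)
  novl <- sum(overlaps_any(enriched, candidates))
  nhit <- sum(overlaps_any(candidates, enriched))
  list(n_enriched = ne, n_overlapping = novl,
       pct_enriched_overlapping = if (ne) round(100 * novl / ne, 2) else 0,
       n_candidates = nc, n_candidates_hit = nhit,
       pct_candidates_hit = if (nc) round(100 * nhit / nc, 2) else 0)
}
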