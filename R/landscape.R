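# Recombination-landscape divergence: windowed replicate correlations, the
# PRDI (me - ms) summary, the delta-r Manhattan statistic with its 3-SD
# outlier rule, and local-background hotspot/coldspot calling.

#' Windowed Spearman correlations between replicate recombination tracks
#'
#' For every pair of binned tracks and every genomic window, the Spearman
#' rank correlation of the bin values inside the window. Pairs are
#' classified `within` (same population) or `between`. Bins missing in
#' either member of a pair are dropped pairwise; windows with fewer than
#' `min_pairs` paired bins give `NA`.
#'
#' @param tracks list of binned tracks (shared bin grid; see
#'   [bin_average()]).
#' @param populations character vector, one population label per track.
#' @param window window width in bp (a multiple of the bin width).
#' @param min_pairs minimum paired bins per window (default 10).
#' @return a correlation panel: `data.table(chrom, win_start, track_i,
#'   track_j, type, pop_pair, rho)` where `type` is `within` or `between`
#'   and `pop_pair` names the population(s) involved.
#' @export
window_spearman <- function(tracks, populations, window = 5e6, min_pairs = 10) {
  stopifnot(length(tracks) == length(populations), length(tracks) >= 2)
  bw <- attr(tracks[[1]], "width")
  if (!is.null(bw) && window %% bw != 0) {
    stop("window must be a multiple of the bin width")
  }
  grid <- tracks[[1]][, .(chrom, start, end)]
  for (t in tracks[-1]) {
    if (!identical(t[, .(chrom, start, end)], grid)) {
      stop("tracks must share one bin grid")
    }
  }
  vals <- vapply(tracks, function(t) t$value, numeric(nrow(grid)))
  win_start <- floor(grid$start / window) * window
  idx <- split(seq_len(nrow(grid)), list(grid$chrom, win_start), drop = TRUE)
  combs <- utils::combn(length(tracks), 2)
  out <- rbindlist(lapply(idx, function(ii) {
    ch <- grid$chrom[ii[1]]
    ws <- win_start[ii[1]]
    rho <- vapply(seq_len(ncol(combs)), function(k) {
      a <- vals[ii, combs[1, k]]; b <- vals[ii, combs[2, k]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < min_pairs) return(NA_real_)
      cor(a[ok], b[ok], method = "spearman")
    }, numeric(1))
    data.table(chrom = ch, win_start = ws,
               track_i = combs[1, ], track_j = combs[2, ], rho = rho)
  }))
  out[, type := ifelse(populations[track_i] == populations[track_j],
                       "within", "between")]
  out[, pop_pair := ifelse(type == "within", populations[track_i],
                           paste(pmin(populations[track_i], populations[track_j]),
                                 pmax(populations[track_i], populations[track_j]),
                                 sep = ":"))]
  setorder(out, chrom, win_start, track_i, track_j)
  out[]
}

#' Empirical (or simulated) landscape-divergence metric
#'
#' `me = min over populations of median(within-population rho) -
#' median(between-population rho)`, with medians pooled over all windows and
#' replicate pairs. Computed on empirical maps it is the empirical
#' divergence *me*; computed on maps from neutral simulations with a shared
#' landscape it is the neutral divergence *ms*.
#'
#' @param panel a correlation panel from [window_spearman()].
#' @return list with `me`, the per-population within medians
#'   (`within_medians`) and the between median (`between_median`).
#' @export
compute_me <- function(panel) {
  w <- panel[type == "within" & !is.na(rho)]
  b <- panel[type == "between" & !is.na(rho)]
  if (nrow(w) == 0L || nrow(b) == 0L) {
    stop("panel must contain non-missing within and between correlations")
  }
  wm <- w[, .(med = median(rho)), by = pop_pair]
  me <- min(wm$med) - median(b$rho)
  list(me = me,
       within_medians = setNames(wm$med, wm$pop_pair),
       between_median = median(b$rho))
}

#' Population Recombination Divergence Index
#'
#' `PRDI = me - ms`: the part of the between-population drop in
#' recombination-map correlation that neutral replicate estimation under a
#' shared landscape does not explain.
#'
#' @param me empirical divergence (scalar or result of [compute_me()]).
#' @param ms neutral/simulated divergence (same form).
#' @return list with `me`, `ms` and `prdi = me - ms`.
#' @export
compute_prdi <- function(me, ms) {
  if (is.list(me)) me <- me$me
  if (is.list(ms)) ms <- ms$me
  list(me = me, ms = ms, prdi = me - ms)
}

#' Per-window PRDI profile
#'
#' Applies the `me - ms` contrast within each correlation window, giving a
#' genomic profile of landscape divergence.
#'
#' @param empirical,neutral correlation panels from [window_spearman()] on
#'   the same window grid.
#' @return `data.table(chrom, win_start, me, ms, prdi)`.
#' @export
prdi_profile <- function(empirical, neutral) {
  one <- function(panel) {
    panel[!is.na(rho),
          .(val = {
            wm <- .SD[type == "within", median(rho), by = pop_pair]$V1
            bt <- rho[type == "between"]
            if (length(wm) && length(bt)) min(wm) - median(bt) else NA_real_
          }),
          by = .(chrom, win_start)][!is.na(val)]
  }
  e <- one(empirical)[, .(chrom, win_start, me = val)]
  s <- one(neutral)[, .(chrom, win_start, ms = val)]
  out <- merge(e, s, by = c("chrom", "win_start"), all = FALSE)
  out[, prdi := me - ms]
  setorder(out, chrom, win_start)
  out[]
}

#' Windowed Manhattan dissimilarity between two recombination tracks
#'
#' For each non-overlapping window of `n_bins` complete bins,
#' `delta_r = log((1/n_bins) * sum |a_i - b_i| + eps)` (natural log). Windows
#' containing any missing or incomplete bin are dropped.
#'
#' @param a,b binned tracks on a shared 2 kb grid.
#' @param window window width in bp (default 100 kb = 50 bins of 2 kb).
#' @param eps floor added before the log (default 1e-12).
#' @return `data.table(chrom, win_start, delta_r)`.
#' @export
delta_r <- function(a, b, window = 1e5, eps = 1e-12) {
  stopifnot(identical(a[, .(chrom, start, end)], b[, .(chrom, start, end)]))
  bw <- attr(a, "width")
  if (is.null(bw)) bw <- as.numeric(stats::median(a$end - a$start))
  n_bins <- window / bw
  if (n_bins != round(n_bins)) stop("window must be a multiple of the bin width")
  d <- data.table(chrom = a$chrom, start = a$start,
                  complete = (a$end - a$start) == bw,
                  adiff = abs(a$value - b$value))
  d[, win_start := floor(start / window) * window]
  out <- d[, .(delta_r = if (.N == n_bins && all(complete) && !anyNA(adiff))
                 log(sum(adiff) / n_bins + eps) else NA_real_),
           by = .(chrom, win_start)]
  out <- out[!is.na(delta_r)]
  setorder(out, chrom, win_start)
  out[]
}

#' Delta-r divergence outliers
#'
#' Computes per-window medians of the within-population and
#' between-population delta-r values and flags windows whose between median
#' exceeds the genome-wide mean of the within medians by more than
#' `z` SDs.
#'
#' @param within `data.table(chrom, win_start, delta_r)` stacked over all
#'   within-population track pairs.
#' @param between same for between-population pairs.
#' @param z SD multiplier (default 3).
#' @return list with `windows` (`data.table` of per-window medians, the
#'   threshold and flags) and `outliers` (region set of flagged windows).
#' @export
delta_r_outliers <- function(within, between, z = 3, window = 1e5) {
  wmed <- within[, .(med_within = median(delta_r)), by = .(chrom, win_start)]
  bmed <- between[, .(med_between = median(delta_r)), by = .(chrom, win_start)]
  thr <- mean(wmed$med_within) + z * sd(wmed$med_within)
  win <- merge(wmed, bmed, by = c("chrom", "win_start"))
  win[, outlier := med_between > thr]
  setattr(win, "threshold", thr)
  out <- win[outlier == TRUE]
  list(windows = win[],
       threshold = thr,
       outliers = if (nrow(out)) regions(out$chrom, out$win_start,
                                         out$win_start + window)
                  else regions(character(), numeric(), numeric()))
}

# floor zero rates at (smallest positive rate) * 1e-3 before log
.floor_log <- function(rate) {
  pos <- rate[rate > 0]
  if (length(pos) == 0L) stop("track has no positive rates")
  log(pmax(rate, min(pos) * 1e-3))
}

#' Call recombination hotspots and coldspots
#'
#' Compares each bin's log rate with the mean and SD of log rates in a local
#' +/- `half_window` background. The background excludes the focal bin and a
#' two-bin guard ring on each side, so that a genuine spot spanning a few
#' adjacent bins does not inflate its own background SD and mask itself
#' (mean/SD backgrounds are not robust to contamination). Bins more than `z`
#' SDs above (below) the local mean are hotspot (coldspot) seeds; adjacent
#' seed bins of the same kind are merged with a `merge_gap` maximum gap, and
#' hotspots longer than `hotspot_max_len` are removed (long hotspots are a
#' known artefact of LD-based maps). At chromosome ends the truncated
#' background is used, requiring at least `min_background` bins.
#'
#' @param track binned track of recombination rates (2 kb grid).
#' @param half_window background half-width in bp (default 20 kb).
#' @param z SD threshold (default 3).
#' @param merge_gap maximum merge gap in bp (default 1 kb).
#' @param hotspot_max_len maximum retained hotspot length (default 5 kb).
#' @param min_background minimum background bins (default 5).
#' @return `data.table(chrom, start, end, kind, peak_z)`; one row per merged
#'   spot, `kind` in `hotspot`/`coldspot`, `peak_z` the most extreme bin z.
#' @export
call_spots <- function(track, half_window = 20000, z = 3, merge_gap = 1000,
                       hotspot_max_len = 5000, min_background = 5) {
  bw <- attr(track, "width")
  if (is.null(bw)) bw <- as.numeric(stats::median(track$end - track$start))
  half_bins <- ceiling(half_window / bw)
  x <- as.data.table(track)[!is.na(value)]
  x[, lograte := .floor_log(value), by = chrom]
  x[, zscore := {
    v <- lograte; n <- .N
    zz <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      j <- setdiff(max(1, i - half_bins):min(n, i + half_bins),
                   (i - 2):(i + 2))
      if (length(j) < min_background) next
      s <- sd(v[j])
      if (is.finite(s) && s > 0) zz[i] <- (v[i] - mean(v[j])) / s
    }
    zz
  }, by = chrom]
  x[, kind := fifelse(is.na(zscore), NA_character_,
                      fifelse(zscore > z, "hotspot",
                              fifelse(zscore < -z, "coldspot", NA_character_)))]
  seeds <- x[!is.na(kind)]
  if (nrow(seeds) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      kind = character(), peak_z = numeric()))
  }
  out <- rbindlist(lapply(c("hotspot", "coldspot"), function(k) {
    s <- seeds[kind == k]
    if (nrow(s) == 0L) return(NULL)
    m <- merge_regions(regions(s$chrom, s$start, s$end), max_gap = merge_gap)
    hits <- .olap_pairs(m, regions(s$chrom, s$start, s$end, score = s$zscore))
    pk <- hits[, .(peak_z = s$zscore[yid][which.max(abs(s$zscore[yid]))]),
               by = xid]
    m[, kind := k]
    m[pk$xid, peak_z := pk$peak_z]
    m
  }))
  out <- out[!(kind == "hotspot" & end - start > hotspot_max_len)]
  setorder(out, chrom, start)
  out[]
}

#' Hotspot/coldspot sharing summary
#'
#' Counts spots of set `a` overlapping (>= 1 bp) any spot of set `b` and
#' reports the sharing percentages under the three conventions in use:
#' shared as a fraction of `a`, of `b`, and of `a + b`.
#'
#' @param a,b spot call sets (region sets; same kind in both).
#' @return list with `n_a`, `n_b`, `shared` and integer-rounded
#'   `pct_of_a`, `pct_of_b`, `pct_of_total`.
#' @export
sharing_summary <- function(a, b) {
  shared <- sum(overlaps_any(a, b))
  pct <- function(x, d) if (d > 0) round(100 * x / d) else 0
  list(n_a = nrow(a), n_b = nrow(b), shared = shared,
       pct_of_a = pct(shared, nrow(a)),
       pct_of_b = pct(sum(overlaps_any(b, a)), nrow(b)),
       pct_of_total = pct(shared, nrow(a) + nrow(b)))
}
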