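#' Region sets
#'
#' A region set is a `data.table` with columns `chrom`, `start`, `end`
#' (0-based half-open) and optional `label` and `score` columns. Hotspots,
#' coldspots, outlier windows and candidate "repeated regions" are all
#' carried as region sets.
#'
#' @param chrom chromosome names.
#' @param start,end half-open interval bounds, `start < end`.
#' @param label,score optional per-region annotation.
#' @return a `data.table` region set, sorted by (`chrom`, `start`).
#' @export
regions <- function(chrom, start, end, label = NULL, score = NULL) {
  out <- data.table(chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end))
  if (!is.null(label)) out[, label := label]
  if (!is.null(score)) out[, score := score]
  validate_regions(out)
  setkey(out, chrom, start, end)
  out[]
}

validate_regions <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start >= x$end)) {
    stop("regions must satisfy start < end (half-open)")
  }
  invisible(x)
}

# half-open overlap: [s1,e1) and [s2,e2) share >= 1 base
.olap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.table(xid = integer(), yid = integer()))
  }
  ad <- data.table(chrom = a$chrom, start = a$start, end = a$end - 1L,
                   xid = seq_len(nrow(a)))
  bd <- data.table(chrom = b$chrom, start = b$start, end = b$end - 1L,
                   yid = seq_len(nrow(b)))
  setkey(bd, chrom, start, end)
  ov <- foverlaps(ad, bd, type = "any", nomatch = NULL)
  ov[, .(xid, yid)]
}

#' Intersect two region sets
#'
#' Overlap is defined as sharing at least one base; touching half-open
#' intervals (`[0,100)` vs `[100,200)`) do not overlap.
#'
#' @param a,b region sets (see [regions()]).
#' @return list with `pairs` (a `data.table` of overlapping index pairs
#'   `xid` into `a`, `yid` into `b`) and `a_hits` (logical, per region of
#'   `a`, whether it overlaps any region of `b`).
#' @export
intersect_regions <- function(a, b) {
  validate_regions(a); validate_regions(b)
  pairs <- .olap_pairs(a, b)
  hits <- rep(FALSE, nrow(a))
  hits[unique(pairs$xid)] <- TRUE
  list(pairs = pairs, a_hits = hits)
}

#' Count / flag overlaps of one region set with another
#'
#' @param a,b region sets.
#' @return logical vector along `a`: does each region of `a` overlap any
#'   region of `b`?
#' @export
overlaps_any <- function(a, b) intersect_regions(a, b)$a_hits

#' Merge nearby regions
#'
#' Regions on the same chromosome whose gap is at most `max_gap` bp are
#' unioned. With `max_gap = 0`, adjacent half-open regions
#' (`[0,x)`, `[x,y)`) merge but regions separated by >= 1 bp do not.
#'
#' @param x region set.
#' @param max_gap maximum gap (bp, >= 0) to bridge.
#' @return merged region set, sorted and non-overlapping. Idempotent.
#' @export
merge_regions <- function(x, max_gap = 0) {
  validate_regions(x)
  stopifnot(max_gap >= 0)
  if (nrow(x) == 0L) return(regions(character(), numeric(), numeric()))
  y <- x[order(chrom, start, end), .(chrom, start, end)]
  y[, {
    cm <- cummax(shift(end, fill = start[1]))
    grp <- cumsum(start - cm > max_gap)
    .SD[, .(start = min(start), end = max(end)), by = .(newgrp = grp)][, newgrp := NULL]
  }, by = chrom][]
}

#' Total genome length covered by a region set
#' @param x region set (overlaps are collapsed first).
#' @return total covered bp.
#' @export
covered_bp <- function(x) {
  m <- merge_regions(x, max_gap = 0)
  sum(m$end - m$start)
}

#' Randomly reposition regions within their chromosomes
#'
#' Places each region at a uniform start in `[0, chrom_len - region_len]` on
#' its own chromosome, preserving its length. Regions are repositioned
#' independently; permuted regions may overlap one another. This is the null
#' model for the interval permutation tests (chromosome identity and size
#' preserved).
#'
#' @param x region set.
#' @param layout a [genome_layout()].
#' @return region set of the same lengths/chromosomes at random positions.
#' @export
shuffle_regions <- function(x, layout) {
  validate_regions(x)
  if (nrow(x) == 0L) return(copy(x))
  len <- x$end - x$start
  clen <- chrom_length(layout, x$chrom)
  if (any(len > clen)) stop("region longer than its chromosome")
  s <- floor(runif(nrow(x)) * (clen - len + 1))
  data.table(chrom = x$chrom, start = s, end = s + len)
}
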