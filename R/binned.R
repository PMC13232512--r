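#' Average a recombination map over fixed-width bins
#'
#' Computes, for every bin of the genome tiling, the length-weighted mean of
#' the map's rate over the bases of the bin that the map covers (the
#' semantics of `bedtools map -o mean` over per-base rates). Bins with no
#' covering interval get `NA`. The last bin of a chromosome may be shorter
#' than `width`; it is kept (callers that require complete bins drop it).
#'
#' @param map a `recmap` (see [read_recmap()]).
#' @param width bin width in bp.
#' @param layout optional [genome_layout()]; if omitted the layout is taken
#'   from the map's own extent per chromosome.
#' @return a binned track: `data.table(chrom, start, end, value)` with
#'   attribute `width`.
#' @export
bin_average <- function(map, width, layout = NULL) {
  stopifnot(width > 0)
  if (is.null(layout)) {
    if (nrow(map) == 0L) {
      out <- data.table(chrom = character(), start = numeric(),
                        end = numeric(), value = numeric())
      setattr(out, "width", width)
      return(out[])
    }
    ext <- as.data.table(map)[, .(length = max(end)), by = chrom]
    layout <- genome_layout(ext$chrom, ext$length)
  }
  bins <- tile_genome(layout, width)
  bins[, bin := .I]
  m <- as.data.table(map)[, .(chrom, start, end, rate)]
  if (nrow(m) == 0L) {
    out <- bins[, .(chrom, start, end, value = NA_real_)]
    setattr(out, "width", width)
    return(out[])
  }
  # closed-coordinate shadow for half-open overlap
  bq <- bins[, .(chrom, start, end = end - 1L, bin, bstart = start, bend = end)]
  mq <- m[, .(chrom, start, end = end - 1L, rate, mstart = start, mend = end)]
  setkey(mq, chrom, start, end)
  ov <- foverlaps(bq, mq, type = "any", nomatch = NULL)
  ov[, cov_len := pmin(bend, mend) - pmax(bstart, mstart)]
  agg <- ov[, .(value = sum(rate * cov_len) / sum(cov_len)), by = bin]
  out <- bins[, .(chrom, start, end, bin)]
  out[agg, value := i.value, on = "bin"]
  out[, bin := NULL]
  setattr(out, "width", width)
  out[]
}

# internal: join a value from a windowed table (e.g. linkage map) onto a bin
# grid by maximal overlap
value_at_bins <- function(bins, windows, value_col) {
  b <- as.data.table(bins)[, .(chrom, start, end)]
  b[, bin := .I]
  w <- as.data.table(windows)
  bq <- b[, .(chrom, start, end = end - 1L, bin, bstart = start, bend = end)]
  wq <- w[, .(chrom, start, end = end - 1L, val = get(value_col),
              wstart = start, wend = end)]
  setkey(wq, chrom, start, end)
  ov <- foverlaps(bq, wq, type = "any", nomatch = NULL)
  ov[, cov_len := pmin(bend, wend) - pmax(bstart, wstart)]
  best <- ov[order(bin, -cov_len)][, .SD[1L], by = bin]
  out <- b[, .(bin)]
  out[best, val := i.val, on = "bin"]
  out$val
}
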