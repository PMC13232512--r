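#' Read a recombination map (TSV)
#'
#' Input is a Pyrho-style 4-column TSV: `chrom`, `start`, `end` (0-based
#' half-open), `rate` (per-base per-generation recombination rate).
#' Intervals must be sorted and non-overlapping per chromosome; rates must be
#' finite and non-negative.
#'
#' @param path TSV file path (with or without header line).
#' @param population,subset optional metadata labels stored as attributes.
#' @return a `recmap`: `data.table(chrom, start, end, rate)` with attributes
#'   `population` and `subset`.
#' @export
read_recmap <- function(path, population = NA_character_, subset = NA_integer_) {
  x <- fread(path, header = "auto")
  if (ncol(x) < 4L) stop("recombination map needs >= 4 columns: chrom, start, end, rate")
  x <- x[, 1:4]
  setnames(x, c("chrom", "start", "end", "rate"))
  x[, chrom := as.character(chrom)]
  x[, `:=`(start = as.numeric(start), end = as.numeric(end), rate = as.numeric(rate))]
  as_recmap(x, population = population, subset = subset)
}

#' Construct/validate a recombination map
#'
#' @param x data.frame-like with columns `chrom`, `start`, `end`, `rate`.
#' @inheritParams read_recmap
#' @return validated `recmap` (sorted by chrom, start).
#' @export
as_recmap <- function(x, population = NA_character_, subset = NA_integer_) {
  x <- as.data.table(x)[, .(chrom = as.character(chrom), start, end, rate)]
  if (nrow(x) && any(x$start >= x$end)) stop("map intervals must satisfy start < end")
  if (any(!is.finite(x$rate)) || any(x$rate < 0)) stop("rates must be finite and >= 0")
  setorder(x, chrom, start)
  bad <- x[, any(start[-1] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(bad)) stop("overlapping intervals on: ", paste(bad$chrom, collapse = ", "))
  setattr(x, "population", population)
  setattr(x, "subset", subset)
  setattr(x, "class", c("recmap", class(x)))
  x[]
}

#' Write a recombination map to TSV
#' @param map a `recmap`.
#' @param path output path.
#' @export
write_recmap <- function(map, path) {
  fwrite(as.data.table(map)[, .(chrom, start, end, rate)], path,
         sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a pedigree/linkage recombination map (TSV)
#'
#' Expected columns: `chrom`, `start`, `end` (0-based half-open windows),
#' `cmmb` (recombination rate in cM/Mb). Windows must be non-overlapping per
#' chromosome and rates non-negative.
#'
#' @param path TSV path.
#' @return `data.table(chrom, start, end, cmmb)`.
#' @export
read_linkage_map <- function(path) {
  x <- fread(path)
  if (ncol(x) < 4L) stop("linkage map needs 4 columns: chrom, start, end, cM/Mb")
  x <- x[, 1:4]
  setnames(x, c("chrom", "start", "end", "cmmb"))
  x[, chrom := as.character(chrom)]
  if (any(x$cmmb < 0)) stop("cM/Mb rates must be >= 0")
  setorder(x, chrom, start)
  bad <- x[, any(start[-1] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(bad)) stop("overlapping linkage windows on: ", paste(bad$chrom, collapse = ", "))
  x[]
}

#' Write a linkage map to TSV
#' @param x `data.table(chrom, start, end, cmmb)`.
#' @param path output path.
#' @export
write_linkage_map <- function(x, path) {
  fwrite(as.data.table(x)[, .(chrom, start, end, cmmb)], path,
         sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a BED file as a region set
#'
#' Columns beyond the first three are mapped to `label` (BED name) and
#' `score`.
#'
#' @param path BED path (0-based half-open, tab-separated, no header).
#' @return region set.
#' @export
read_bed <- function(path) {
  x <- fread(path, header = FALSE)
  lbl <- if (ncol(x) >= 4L) as.character(x[[4]]) else NULL
  sco <- if (ncol(x) >= 5L) as.numeric(x[[5]]) else NULL
  regions(x[[1]], x[[2]], x[[3]], label = lbl, score = sco)
}

#' Write a region set as BED
#' @param x region set; `label`/`score` columns become BED columns 4-5.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_regions(x)
  y <- as.data.table(x)[order(chrom, start)]
  cols <- c("chrom", "start", "end")
  if ("label" %in% names(y)) cols <- c(cols, "label")
  if ("score" %in% names(y)) {
    if (!"label" %in% names(y)) y[, label := "."]
    cols <- c("chrom", "start", "end", "label", "score")
  }
  fwrite(y[, ..cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read precomputed pairwise LD records
#'
#' TSV in the dialect of vcftools `--geno-r2`: columns `chrom`, `posA`,
#' `posB`, `r2` (positions 1-based on input, converted to 0-based
#' internally). Pairs farther apart than `max_dist` are dropped (the study's
#' LD computation window).
#'
#' @param path TSV path.
#' @param max_dist maximum pair separation in bp (default 35000).
#' @param one_based are input positions 1-based (default TRUE)?
#' @return `data.table(chrom, posA, posB, r2)`, 0-based, posA < posB.
#' @export
read_ld_table <- function(path, max_dist = 35000, one_based = TRUE) {
  x <- fread(path)
  x <- x[, 1:4]
  setnames(x, c("chrom", "posA", "posB", "r2"))
  x[, chrom := as.character(chrom)]
  if (one_based) x[, `:=`(posA = posA - 1, posB = posB - 1)]
  sw <- x$posA > x$posB
  if (any(sw)) x[sw, `:=`(posA = posB, posB = posA)]
  x <- x[posB - posA <= max_dist]
  if (any(x$r2 < 0 | x$r2 > 1, na.rm = TRUE)) stop("r2 values must lie in [0, 1]")
  x[]
}
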